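# smcseq

ChIP-seq enrichment mapping, pericentromeric spatial statistics and
sister-chromatid segregation timing for SMC complexes (Smc5/6, cohesin)
on the budding-yeast genome.

## The problem

Smc5/6 and cohesin are Structural Maintenance of Chromosomes complexes
whose chromosomal binding pattern carries information about unresolved
sister-chromatid intertwinings — topological links formed during
replication and normally removed by topoisomerase II (Top2). Mapping
where these complexes sit, how tightly their sites cluster around
centromeres, and how pericentromeric enrichment scales with chromosome
and arm length requires a reproducible path from aligned reads to
statistics. `smcseq` implements that path for researchers analysing
yeast ChIP-seq of tagged SMC subunits, together with the live-imaging
timing classifier used to relate binding to chromosome segregation.

## What it computes

**Fold enrichment.** Single-end reads are extended to the predicted
fragment length (150 bp), summed in 10-bp bins, depth-normalized,
smoothed, and expressed per bin as

```
FE(b) = (chip(b) + c) / (wce(b) + c),        c = 0.1
```

where WCE is the whole-cell-extract input.

**Peak calling.** A region is a peak iff (1) FE > 2.0 over a contiguous
run of bins, (2) max normalized ChIP depth over the run > 1.0, and
(3) max fold enrichment of a no-tag control < 1.8 (the false-positive
filter), with a 30-bp minimum width.

**Spatial statistics.** Net enrichment `Σ_b (FE_tag − FE_notag)` in
100-kb windows spanning each centromere (50-kb flanks per arm);
Pearson/Spearman correlation of those values with chromosome length,
arm length, and shortest-arm length (centromere-to-nearest-telomere
distance; the rDNA-bearing chromosome XII is excluded); and an exact
one-sided binomial test of pericentromeric peak clustering:
`p = P(X ≥ k | n, p0)` where `k` of `n` peak midpoints fall in 25-kb
centromere windows covering genome fraction `p0`.

**Segregation timing.** From per-frame live-imaging event tables:
spindle elongation (tubulin structure > 3.18 µm) is time zero;
chromatid separation and mother/bud segregation are classified into
≤5 min, >5 min, never-segregated and never-separated categories over a
70-min span, with missegregation scored at the final frame.

**Synthetic data.** Seeded generators produce a 16-chromosome yeast-like
genome (~12 Mb) with centromeres, convergently transcribed gene pairs
and LTRs, Poisson reads with planted peaks under wild-type-like,
top2-like, cohesin-mutant and uniform placement regimes, and per-cell
imaging trajectories — so the entire pipeline is testable without any
sequencing data.

## Worked example

```r
library(smcseq)

cfg   <- simulationConfig(seed = 3, nChromosomes = 4,
                          minLength = 1.5e5, maxLength = 3e5, nPeaks = 20)
gm    <- makeGenome(cfg)
truth <- plantRegime(gm$genome, "wildtype", config = cfg, nPeaks = 20)
run   <- runChipseq(gm$genome,
                    simulateReads(gm$genome, truth, "chip",  cfg),
                    simulateReads(gm$genome, truth, "wce",   cfg),
                    simulateReads(gm$genome, truth, "notag", cfg))
run$peaks
#> PeakSet 'chip': 20 peaks
#>   params: feThreshold=2, intensityFloor=1, notagCeiling=1.8,
#>   minWidth=30, mode=region, notagUsed=TRUE, pericenWidth=25000
unlist(run$clustering)
#> nPeaks            k           p0            p
#> 2.000000e+01 1.100000e+01 1.172011e-01 3.474239e-06
```

Twenty planted peaks are recovered as twenty called peaks. Eleven of the
twenty peak midpoints fall inside the 25-kb centromere windows, which
cover 11.7% of this small 4-chromosome genome; under uniform placement
that many hits has one-sided exact binomial probability 3.5e-06, so the
pericentromeric clustering is highly significant even at toy scale. On a
full 16-chromosome genome the same wild-type regime yields p-values
around 1e-29.

`runDemo("ci")` runs this end to end for all four placement regimes plus
the timing classifier and returns a structured report. A thin
command-line wrapper over the same functions is installed at
`inst/scripts/smcseq.R` (subcommands `simulate`, `run`, `segtiming`,
`demo`).

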