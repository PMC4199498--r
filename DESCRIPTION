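Package: smcseq
Title: ChIP-Seq Enrichment, Pericentromeric Clustering and Segregation
    Timing for Budding Yeast SMC Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping Structural Maintenance of Chromosomes (SMC)
    complexes such as Smc5/6 and cohesin on the Saccharomyces cerevisiae
    genome from ChIP-seq read alignments. Implements fragment extension,
    fixed-width binning, depth normalization and smoothing, ChIP/WCE fold
    enrichment, a three-criterion peak caller with a no-tag false-positive
    filter, chromosome-arm masking (pericentromeric, subtelomeric and LTR
    exclusions), convergent-gene intergenic annotation, windowed net
    enrichment around centromeres with chromosome/arm-length correlations,
    and an exact binomial test for pericentromeric peak clustering. Also
    classifies per-cell sister-chromatid separation and segregation timing
    relative to spindle elongation from live-imaging event tables, and
    ships seeded generators producing yeast-like synthetic genomes, reads
    and imaging trajectories so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
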