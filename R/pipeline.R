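# End-to-end orchestration: coverage -> fold enrichment -> peak calling ->
# annotation -> spatial statistics, with optional on-disk outputs and a
# machine-readable run manifest.

.defaultParams <- function() {
  list(binSize = 10L, fragLength = 150L, smoothBins = 35L,
       pseudocount = 0.1, feThreshold = 2.0, intensityFloor = 1.0,
       notagCeiling = 1.8, minWidth = 30L, mode = "region",
       intensityRelative = FALSE, pericenWidth = 25000L,
       subtel = 20000L, windowWidth = 100000L, flankWidth = 50000L,
       exclude = "chrXII", normTarget = 1e6)
}

.trackFromReads <- function(reads, genome, p, label) {
  fr <- extendReads(reads, genome, p$fragLength)
  tr <- binCoverage(fr, genome, p$binSize, sample = label)
  tr <- normalizeDepth(tr, target = p$normTarget)
  smoothTrack(tr, p$smoothBins)
}

#' Run the full ChIP-seq enrichment pipeline
#'
#' Executes read extension, binned coverage, depth normalization,
#' smoothing, ChIP/WCE fold enrichment, three-criterion peak calling
#' (with the no-tag false-positive filter when a no-tag sample is given),
#' peak annotation, centromere-window net enrichment, length
#' correlations and the pericentromeric clustering test. When
#' \code{outDir} is given, writes bedGraph tracks, a BED6+ peak file,
#' a window TSV, JSON statistics and a run manifest.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param chipReads,wceReads stranded \code{GRanges} of aligned reads.
#' @param notagReads reads of the no-tag control, or \code{NULL} (then
#'   calling criterion 3 and net-enrichment statistics are skipped with a
#'   warning).
#' @param params named list overriding the stage defaults (bin size 10,
#'   fragment length 150, smoothing 35 bins, fold-enrichment threshold
#'   2.0, intensity floor 1.0, no-tag ceiling 1.8, minimum width 30 bp,
#'   pericentromeric window 25 kb, subtelomere 20 kb, scoring window
#'   100 kb, arm flank 50 kb, chrXII excluded from correlations).
#' @param sample label of the tagged sample.
#' @param outDir optional output directory.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a list bundle: tracks, \code{peaks} (annotated
#'   \linkS4class{PeakSet}), \code{windows}, \code{correlations},
#'   \code{clustering}, \code{params}, \code{manifest}.
#' @export
runChipseq <- function(genome, chipReads, wceReads, notagReads = NULL,
                       params = list(), sample = "chip", outDir = NULL,
                       seed = NA_integer_) {
  stopifnot(is(genome, "GenomeAnnotation"))
  p <- utils::modifyList(.defaultParams(), params)
  chip <- .trackFromReads(chipReads, genome, p, sample)
  wce <- .trackFromReads(wceReads, genome, p, "wce")
  feTag <- foldEnrichment(chip, wce, p$pseudocount)
  feNotag <- NULL
  if (!is.null(notagReads)) {
    notag <- .trackFromReads(notagReads, genome, p, "notag")
    feNotag <- foldEnrichment(notag, wce, p$pseudocount)
  }
  peakSet <- callPeaks(feTag, chip, feNotag,
                       feThreshold = p$feThreshold,
                       intensityFloor = p$intensityFloor,
                       notagCeiling = p$notagCeiling,
                       minWidth = p$minWidth, mode = p$mode,
                       intensityRelative = p$intensityRelative)
  peakSet <- annotatePeaks(peakSet, genome, pericenWidth = p$pericenWidth,
                           pericen = p$pericenWidth, subtel = p$subtel)
  windows <- NULL; correlations <- NULL
  if (!is.null(feNotag)) {
    cwVals <- pericentromericEnrichment(feTag, feNotag, genome,
                                        width = p$windowWidth,
                                        side = "center")
    armVals <- pericentromericEnrichment(feTag, feNotag, genome,
                                         width = p$flankWidth,
                                         side = "arms")
    windows <- list(center = cwVals, arms = armVals)
    correlations <- list(
      chrom_length = tryCatch(
        correlateEnrichment(cwVals, genome, "chrom_length", p$exclude),
        error = function(e) conditionMessage(e)),
      shortest_arm = tryCatch(
        correlateEnrichment(cwVals, genome, "shortest_arm", p$exclude),
        error = function(e) conditionMessage(e)),
      arm_length = tryCatch(
        correlateEnrichment(armVals, genome, "arm_length", p$exclude),
        error = function(e) conditionMessage(e)))
  } else {
    warning("no no-tag sample: net-enrichment statistics skipped")
  }
  clustering <- if (length(peakSet@peaks) > 0)
    pericentromericClusteringTest(peakSet, genome, p$pericenWidth) else NULL
  bundle <- list(chip = chip, wce = wce, feTag = feTag, feNotag = feNotag,
                 peaks = peakSet, windows = windows,
                 correlations = correlations, clustering = clustering,
                 params = p)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      chip = writeTrack(chip, file.path(outDir, "chip.bedgraph")),
      fe = writeTrack(feTag, file.path(outDir, "fe_tag.bedgraph")),
      peaks = writePeaks(peakSet, file.path(outDir, "peaks.bed")))
    if (!is.null(feNotag))
      paths <- c(paths, fe_notag = writeTrack(
        feNotag, file.path(outDir, "fe_notag.bedgraph")))
    if (!is.null(windows)) {
      wdf <- data.frame(chrom = names(windows$center),
                        net = unname(windows$center))
      utils::write.table(wdf, file.path(outDir, "window_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, windows = file.path(outDir, "window_enrichment.tsv"))
    }
    manifest <- list(
      sample = sample, seed = seed, parameters = p,
      nReads = list(chip = length(chipReads), wce = length(wceReads),
                    notag = if (is.null(notagReads)) 0L else
                      length(notagReads)),
      nPeaks = length(peakSet@peaks),
      outputs = as.list(paths),
      md5 = as.list(tools::md5sum(unname(paths))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    bundle$manifest <- manifest
  }
  bundle
}

#' Demonstration run over all placement regimes
#'
#' Generates a synthetic genome, plants peaks under the wildtype, top2,
#' cohesin-mutant and uniform regimes, simulates ChIP/WCE/no-tag reads,
#' runs the full pipeline on each, and classifies simulated imaging
#' trajectories for a wild-type-like and a mutant-like genotype. The
#' \code{"ci"} scale uses a 4-chromosome sub-megabase genome; the
#' \code{"full"} scale a 16-chromosome ~12 Mb genome (there the intensity
#' floor is applied relative to genome-mean coverage, since depth
#' normalization to a fixed total rescales long genomes far below per-bp
#' units).
#'
#' @param scale \code{"ci"} (default) or \code{"full"}.
#' @param seed integer seed.
#' @param outDir optional output directory.
#' @return a report list, one entry per regime plus \code{segtiming}.
#' @export
runDemo <- function(scale = c("ci", "full"), seed = 1L, outDir = NULL) {
  scale <- match.arg(scale)
  cfg <- if (scale == "ci")
    simulationConfig(seed = seed, nChromosomes = 4L, minLength = 1.5e5,
                     maxLength = 3e5, nPeaks = 25L, stickySites = 2L)
  else simulationConfig(seed = seed)
  gm <- makeGenome(cfg)
  genome <- gm$genome
  params <- if (scale == "ci") list() else list(intensityRelative = TRUE)
  report <- list(scale = scale, seed = seed,
                 genome = list(nChrom = length(chromLengths(genome)),
                               totalBp = sum(as.numeric(chromLengths(genome)))))
  regimes <- c("wildtype", "top2", "cohesin_mutant", "uniform")
  for (rg in regimes) {
    nP <- if (rg == "cohesin_mutant") min(cfg$nChromosomes, 16L) else
      cfg$nPeaks
    truth <- plantRegime(genome, rg, nPeaks = nP, config = cfg,
                         seed = seed + match(rg, regimes))
    chipR <- simulateReads(genome, truth, "chip", cfg,
                           seed = seed + 100L + match(rg, regimes))
    wceR <- simulateReads(genome, truth, "wce", cfg,
                          seed = seed + 200L + match(rg, regimes))
    ntR <- simulateReads(genome, truth, "notag", cfg,
                         seed = seed + 300L + match(rg, regimes))
    run <- runChipseq(genome, chipR, wceR, ntR, params = params,
                      sample = rg, seed = seed,
                      outDir = if (is.null(outDir)) NULL else
                        file.path(outDir, rg))
    pk <- run$peaks@peaks
    report[[rg]] <- list(
      nTruth = sum(truth$kind == "peak"),
      nPeaks = length(pk),
      nArmPeaks = if (length(pk)) sum(pk$onArm) else 0L,
      nPericenPeaks = if (length(pk)) sum(pk$pericentromeric) else 0L,
      clustering = run$clustering,
      correlations = if (rg == "wildtype") lapply(
        run$correlations, function(x) if (is.list(x))
          x[c("n", "pearson", "spearman")] else x) else NULL)
  }
  # Smc6-like and Scc1-like samples sharing planted sites: arm overlap
  truthW <- plantRegime(genome, "top2", nPeaks = cfg$nPeaks, config = cfg,
                        seed = seed + 11L)
  mkPeaks <- function(sampleSeed) {
    chipR <- simulateReads(genome, truthW, "chip", cfg, seed = sampleSeed)
    wceR <- simulateReads(genome, truthW, "wce", cfg, seed = sampleSeed + 1L)
    ntR <- simulateReads(genome, truthW, "notag", cfg, seed = sampleSeed + 2L)
    runChipseq(genome, chipR, wceR, ntR, params = params)$peaks
  }
  pkA <- mkPeaks(seed + 400L)
  pkB <- mkPeaks(seed + 500L)
  report$overlapSharedSites <- overlapPeaks(
    pkA, pkB, restrictTo = armRegions(genome))
  # segregation timing for two genotypes
  wt <- simulateTrajectories(if (scale == "ci") 100L else 500L,
                             params = list(), seed = seed + 600L)
  mut <- simulateTrajectories(if (scale == "ci") 100L else 500L,
                              params = list(sepDelayMean = 8, sepDelaySD = 4,
                                            latencyMean = 10, latencySD = 5,
                                            pNeverSeparate = 0.15,
                                            pNeverSegregate = 0.2),
                              seed = seed + 700L)
  segReport <- lapply(list(wildtype = wt, mutant = mut), function(sim) {
    oc <- classifyCells(sim$frames)
    h <- aggregateHistogram(oc)
    list(nCells = nrow(oc), histogram = h$histogram,
         neverSeparated = h$neverSeparated,
         missegregationRate = mean(oc$missegregated))
  })
  report$segtiming <- segReport
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      report[setdiff(names(report), regimes)],
      file.path(outDir, "demo_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  }
  report
}
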