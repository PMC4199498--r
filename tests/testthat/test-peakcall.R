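gPk <- toyGenome(c(chr1 = 1000L), cenMid0 = c(chr1 = 500L))

mkTracks <- function(fe, chip, notag = NULL, genome = gPk, chrom = "chr1") {
  n <- length(fe)
  stopifnot(n == GenomeInfoDb::seqlengths(genome@seqinfo)[[chrom]] / 10)
  list(
    fe = toyTrack(stats::setNames(list(fe), chrom), 10L, genome,
                  normalized = TRUE, enrichment = TRUE),
    chip = toyTrack(stats::setNames(list(chip), chrom), 10L, genome,
                    normalized = TRUE),
    notag = if (is.null(notag)) NULL else
      toyTrack(stats::setNames(list(notag), chrom), 10L, genome,
               normalized = TRUE, enrichment = TRUE))
}

test_that("a contiguous run passing all three criteria becomes one peak", {
  fe <- rep(1, 100); fe[41:43] <- c(2.5, 3.0, 2.2)
  chip <- rep(0.5, 100); chip[42] <- 4.0
  notag <- rep(1.0, 100)
  tr <- mkTracks(fe, chip, notag)
  ps <- callPeaks(tr$fe, tr$chip, tr$notag)
  pk <- peaks(ps)
  expect_equal(length(pk), 1L)
  expect_equal(c(start(pk), end(pk)), c(401L, 430L))  # 30 bp
  expect_equal(pk$maxFE, 3.0)
  expect_equal(pk$maxChip, 4.0)
  expect_equal(pk$maxNotagFE, 1.0)
})

test_that("the no-tag ceiling rejects false-positive regions", {
  fe <- rep(1, 100); fe[41:44] <- 3
  chip <- rep(2, 100)
  notag <- rep(1, 100); notag[42] <- 1.9
  tr <- mkTracks(fe, chip, notag)
  expect_equal(length(peaks(callPeaks(tr$fe, tr$chip, tr$notag))), 0L)
  # same region passes once the no-tag excursion is below the ceiling
  notag[42] <- 1.7
  tr2 <- mkTracks(fe, chip, notag)
  expect_equal(length(peaks(callPeaks(tr2$fe, tr2$chip, tr2$notag))), 1L)
})

test_that("flat enrichment yields an empty PeakSet and a warning without no-tag", {
  tr <- mkTracks(rep(1, 100), rep(2, 100), rep(1, 100))
  expect_equal(length(peaks(callPeaks(tr$fe, tr$chip, tr$notag))), 0L)
  fe <- rep(1, 100); fe[41:44] <- 3
  tr2 <- mkTracks(fe, rep(2, 100))
  expect_warning(ps <- callPeaks(tr2$fe, tr2$chip, NULL), "criterion")
  expect_equal(length(peaks(ps)), 1L)   # criterion 3 skipped
})

test_that("caller matches the brute-force oracle on random triple tracks", {
  set.seed(101)
  for (rep in 1:40) {
    fe <- round(runif(100, 0.5, 3.5), 2)
    chip <- round(runif(100, 0, 4), 2)
    notag <- round(runif(100, 0.5, 2.5), 2)
    tr <- mkTracks(fe, chip, notag)
    ps <- peaks(callPeaks(tr$fe, tr$chip, tr$notag))
    oracle <- bruteForceCalls(fe, chip, notag)
    expect_equal(length(ps), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(start(ps), (oracle[, 1] - 1L) * 10L + 1L)
      expect_equal(end(ps), oracle[, 2] * 10L)
    }
  }
})

test_that("peak counts are monotone in the thresholds", {
  set.seed(55)
  fe <- round(runif(100, 0.5, 4), 2)
  chip <- round(runif(100, 0, 4), 2)
  notag <- round(runif(100, 0.5, 2.5), 2)
  tr <- mkTracks(fe, chip, notag)
  nAt <- function(thr, ceil) length(peaks(callPeaks(
    tr$fe, tr$chip, tr$notag, feThreshold = thr, notagCeiling = ceil)))
  expect_true(all(diff(sapply(c(1.5, 2, 2.5, 3), nAt, ceil = 1.8)) <= 0))
  expect_true(all(diff(sapply(c(1.2, 1.5, 1.8, 2.2),
                              function(cl) nAt(2, cl))) >= 0))
})

test_that("every reported peak re-checks against the three criteria bin by bin", {
  cfg <- simulationConfig(seed = 31, nChromosomes = 2, minLength = 1.2e5,
                          maxLength = 1.6e5, nPeaks = 8)
  gm <- makeGenome(cfg)
  truth <- plantRegime(gm$genome, "wildtype", config = cfg, nPeaks = 8)
  run <- runChipseq(gm$genome,
                    simulateReads(gm$genome, truth, "chip", cfg),
                    simulateReads(gm$genome, truth, "wce", cfg),
                    simulateReads(gm$genome, truth, "notag", cfg))
  pk <- peaks(run$peaks)
  expect_gt(length(pk), 0L)
  for (i in seq_along(pk)) {
    ch <- as.character(seqnames(pk))[i]
    fb <- (start(pk)[i] - 1L) %/% 10L + 1L
    lb <- (end(pk)[i] - 1L) %/% 10L + 1L
    expect_true(all(trackValues(run$feTag, ch)[fb:lb] > 2.0))
    expect_gt(max(trackValues(run$chip, ch)[fb:lb]), 1.0)
    expect_lt(max(trackValues(run$feNotag, ch)[fb:lb]), 1.8)
    expect_gte(end(pk)[i] - start(pk)[i] + 1L, 30L)
  }
})

test_that("annotation flags follow peak midpoints and generator truth", {
  genes <- data.frame(chrom = "chr1",
                      start0 = c(100000L, 102000L),
                      end0 = c(101500L, 103500L),
                      strand = c("+", "-"))
  g <- toyGenome(c(chr1 = 500000L), cenMid0 = c(chr1 = 250000L),
                 genes = genes)
  mk <- function(s, e) new("PeakSet", peaks = {
    p <- GRanges("chr1", IRanges(s, e), maxFE = 3, maxChip = 2,
                 maxNotagFE = 1)
    GenomeInfoDb::seqlevels(p) <- "chr1"
    GenomeInfoDb::seqinfo(p) <- g@seqinfo
    p
  }, sample = "t")
  near <- annotatePeaks(mk(251900L, 252100L), g)  # 2 kb from the centromere
  expect_true(peaks(near)$pericentromeric)
  expect_false(peaks(near)$onArm)
  sub <- annotatePeaks(mk(10001L, 10200L), g)     # inside the 20-kb subtelomere
  expect_false(peaks(sub)$onArm)
  conv <- annotatePeaks(mk(101600L, 101900L), g)  # the convergent gap
  expect_true(peaks(conv)$convergentIntergenic)
  expect_true(peaks(conv)$onArm)
  expect_equal(peaks(conv)$distToCen,
               abs((101600 - 1 + 101900) %/% 2 - 250000))

  # flags over a synthetic truth set match the generator's labels
  cfg <- simulationConfig(seed = 13, nChromosomes = 3, minLength = 1.2e5,
                          maxLength = 2e5, nPeaks = 15)
  gm <- makeGenome(cfg)
  truth <- plantRegime(gm$genome, "wildtype", config = cfg, nPeaks = 15)
  ps <- annotatePeaks(peakSetFromTruth(truth, gm$genome), gm$genome)
  tr <- GenomicRanges::sort(truth[truth$kind == "peak"],
                            ignore.strand = TRUE)
  expect_equal(peaks(ps)$pericentromeric, tr$pericentromeric)
  expect_true(all(peaks(ps)$convergentIntergenic))
})

test_that("cohesin-mutant truth peaks are all pericentromeric by construction", {
  cfg <- simulationConfig(seed = 17, nChromosomes = 4, minLength = 1.2e5,
                          maxLength = 2e5)
  gm <- makeGenome(cfg)
  truth <- plantRegime(gm$genome, "cohesin_mutant", nPeaks = 4, config = cfg)
  expect_true(all(truth$pericentromeric[truth$kind == "peak"]))
})

test_that("overlap summaries are symmetric, exact and oracle-checked", {
  g <- toyGenome(c(chr1 = 100000L), cenMid0 = c(chr1 = 50000L))
  mkPS <- function(starts, widths) {
    p <- GRanges("chr1", IRanges(starts, width = widths),
                 maxFE = 3, maxChip = 2, maxNotagFE = 1)
    GenomeInfoDb::seqlevels(p) <- "chr1"
    GenomeInfoDb::seqinfo(p) <- g@seqinfo
    new("PeakSet", peaks = GenomicRanges::sort(p, ignore.strand = TRUE),
        sample = "x")
  }
  a <- mkPS(c(100, 5000, 20000), c(300, 300, 500))
  same <- overlapPeaks(a, a)
  expect_equal(same$fracA, 1); expect_equal(same$jaccard, 1)
  disj <- overlapPeaks(a, mkPS(c(40000, 60000), c(200, 200)))
  expect_equal(disj$aInB, 0L); expect_equal(disj$jaccard, 0)

  set.seed(9)
  for (rep in 1:10) {
    sa <- sort(sample(seq(1, 90000, by = 700), 20))
    sb <- sort(sample(seq(1, 90000, by = 900), 15))
    A <- mkPS(sa, 300); B <- mkPS(sb, 400)
    ov <- overlapPeaks(A, B)
    # O(n^2) all-pairs oracle
    hitA <- sum(sapply(seq_along(sa), function(i)
      any(sa[i] <= sb + 399 & sa[i] + 299 >= sb)))
    hitB <- sum(sapply(seq_along(sb), function(j)
      any(sb[j] <= sa + 299 & sb[j] + 399 >= sa)))
    expect_equal(ov$aInB, hitA)
    expect_equal(ov$bInA, hitB)
    rev <- overlapPeaks(B, A)
    expect_equal(ov$jaccard, rev$jaccard)
    expect_equal(ov$overlapBp, rev$overlapBp)
  }
})

test_that("peak sets survive a BED6+ round trip", {
  cfg <- simulationConfig(seed = 19, nChromosomes = 2, minLength = 1.2e5,
                          maxLength = 1.5e5, nPeaks = 6)
  gm <- makeGenome(cfg)
  truth <- plantRegime(gm$genome, "wildtype", config = cfg, nPeaks = 6)
  run <- runChipseq(gm$genome,
                    simulateReads(gm$genome, truth, "chip", cfg),
                    simulateReads(gm$genome, truth, "wce", cfg),
                    simulateReads(gm$genome, truth, "notag", cfg))
  path <- tempfile(fileext = ".bed")
  writePeaks(run$peaks, path)
  back <- readPeaks(path, gm$genome)
  expect_identical(granges(peaks(back)), granges(peaks(run$peaks)))
  expect_equal(peaks(back)$maxFE, peaks(run$peaks)$maxFE, tolerance = 1e-9)
  expect_equal(peaks(back)$pericentromeric, peaks(run$peaks)$pericentromeric)
})
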