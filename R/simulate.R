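# Seeded generators emulating the study's inputs: a 16-chromosome
# yeast-like genome with centromeres, convergently transcribed gene pairs
# and LTRs; Poisson ChIP/WCE/no-tag reads with planted enrichment peaks
# under several placement regimes; and per-cell imaging trajectories.

#' Simulation configuration with yeast-like defaults
#'
#' @param seed integer seed; every generator derives its randomness from
#'   it.
#' @param nChromosomes number of chromosomes (default 16).
#' @param minLength,maxLength chromosome length range in bp (defaults
#'   200 kb to 1.3 Mb, totalling roughly 12 Mb over 16 chromosomes).
#' @param geneLength,geneGap ORF length and intergenic gap in bp
#'   (defaults 1500/500, i.e. one gene per 2 kb as in S. cerevisiae).
#' @param convergentFraction target fraction of adjacent gene pairs in
#'   convergent (+ then -) orientation (default 0.25; at most 0.5).
#' @param ltrProb probability an eligible non-convergent intergenic gap
#'   hosts an LTR (default 0.1).
#' @param ltrLength LTR element length in bp (default 330).
#' @param cenLength centromere length in bp (default 120, the size of a
#'   yeast point centromere).
#' @param cenPositionRange centromere midpoint as a fraction of
#'   chromosome length, drawn uniformly (default 0.15-0.5 so shortest-arm
#'   length varies between chromosomes).
#' @param backgroundDepth mean per-bp fragment coverage of the background
#'   (default 20x).
#' @param fragLength,readLength fragment and read lengths in bp
#'   (defaults 150/50).
#' @param binSize coverage bin width in bp (default 10).
#' @param peakFold fold enrichment of planted peaks (default 5).
#' @param peakWidth planted peak width in bp (default 300).
#' @param nPeaks number of planted peaks (default 150).
#' @param centromereWeight sampling weight of convergent sites inside the
#'   pericentromeric window under the wildtype regime (default 50; the
#'   wild-type pattern is near-exclusive pericentromeric clustering).
#' @param armWeight the same weight under the top2 regime (default 5;
#'   sites also spread along arms).
#' @param stickySites number of sticky-artifact sites enriched in every
#'   immunoprecipitated sample including the no-tag control (default 3);
#'   these exercise the caller's false-positive filter.
#' @param stickyFold fold enrichment at sticky sites (default 5).
#' @param pericenWidth pericentromeric window width in bp (default 25000).
#' @return a named list.
#' @export
simulationConfig <- function(seed = 1L, nChromosomes = 16L,
                             minLength = 2e5, maxLength = 1.3e6,
                             geneLength = 1500L, geneGap = 500L,
                             convergentFraction = 0.25,
                             ltrProb = 0.1, ltrLength = 330L,
                             cenLength = 120L,
                             cenPositionRange = c(0.15, 0.5),
                             backgroundDepth = 20,
                             fragLength = 150L, readLength = 50L,
                             binSize = 10L,
                             peakFold = 5, peakWidth = 300L,
                             nPeaks = 150L,
                             centromereWeight = 50, armWeight = 5,
                             stickySites = 3L, stickyFold = 5,
                             pericenWidth = 25000L) {
  stopifnot(convergentFraction >= 0, convergentFraction <= 0.5,
            minLength <= maxLength, backgroundDepth >= 0)
  as.list(environment())
}

.romanChrom <- function(i) paste0("chr", as.character(utils::as.roman(i)))

#' Generate a yeast-like synthetic genome annotation
#'
#' Chromosome lengths are drawn uniformly from the configured range; each
#' chromosome gets one centromere at an asymmetric position, genes tiled
#' at the configured pitch with a strand pattern producing the configured
#' convergent-pair fraction, and LTRs dropped into a subset of
#' non-convergent intergenic gaps. The generator records its own list of
#' convergent intergenic regions, kept independently of
#' \code{\link{convergentIntergenicRegions}}.
#'
#' @param config list from \code{\link{simulationConfig}}.
#' @param seed overrides \code{config$seed}.
#' @return list with \code{genome} (a \linkS4class{GenomeAnnotation}) and
#'   \code{truth} (list with \code{convergent}: \code{GRanges} of the
#'   generator's convergent intergenic gaps).
#' @export
makeGenome <- function(config = simulationConfig(), seed = config$seed) {
  set.seed(seed)
  n <- config$nChromosomes
  chroms <- vapply(seq_len(n), .romanChrom, "")
  lens <- as.integer(round(stats::runif(n, config$minLength,
                                        config$maxLength)))
  si <- Seqinfo(seqnames = chroms, seqlengths = lens)
  cenHalf <- config$cenLength %/% 2L
  cenList <- vector("list", n)
  featList <- vector("list", n)
  convList <- vector("list", n)
  q <- 2 * config$convergentFraction    # strand-flip prob giving fraction f
  for (i in seq_len(n)) {
    len <- lens[i]
    frac <- stats::runif(1, config$cenPositionRange[1],
                         config$cenPositionRange[2])
    cenMid0 <- as.integer(round(frac * len))
    cenList[[i]] <- GRanges(chroms[i],
                            IRanges(cenMid0 - cenHalf + 1L,
                                    cenMid0 + (config$cenLength - cenHalf)))
    # tile genes, leaving a clear zone around the centromere
    pitch <- config$geneLength + config$geneGap
    starts0 <- seq.int(config$geneGap, len - config$geneLength - 1L,
                       by = pitch)
    ends0 <- starts0 + config$geneLength
    clear <- !(ends0 > cenMid0 - cenHalf - 400L &
               starts0 < cenMid0 + cenHalf + 400L)
    starts0 <- starts0[clear]; ends0 <- ends0[clear]
    ng <- length(starts0)
    strands <- character(ng)
    strands[1] <- sample(c("+", "-"), 1)
    flips <- stats::runif(ng - 1L) < q
    for (j in seq_len(ng - 1L))
      strands[j + 1L] <- if (flips[j]) setdiff(c("+", "-"), strands[j]) else
        strands[j]
    gr <- GRanges(chroms[i], IRanges(starts0 + 1L, ends0),
                  strand = strands)
    gr$kind <- "gene"
    gr$id <- sprintf("%s_gene%04d", chroms[i], seq_len(ng))
    # generator's own convergent-gap bookkeeping
    j <- seq_len(ng - 1L)
    isConv <- strands[j] == "+" & strands[j + 1L] == "-" &
      starts0[j + 1L] - ends0[j] > 0L
    if (any(isConv)) {
      cj <- which(isConv)
      convList[[i]] <- GRanges(chroms[i],
                               IRanges(ends0[cj] + 1L, starts0[cj + 1L]))
    }
    # LTRs in a subset of the remaining gaps
    gapOk <- which(!isConv &
                     starts0[j + 1L] - ends0[j] >= config$ltrLength + 20L)
    if (length(gapOk)) {
      take <- gapOk[stats::runif(length(gapOk)) < config$ltrProb]
      if (length(take)) {
        gapMid0 <- (ends0[take] + starts0[take + 1L]) %/% 2L
        lhalf <- config$ltrLength %/% 2L
        ltr <- GRanges(chroms[i],
                       IRanges(gapMid0 - lhalf + 1L,
                               gapMid0 + (config$ltrLength - lhalf)),
                       strand = sample(c("+", "-"), length(take),
                                       replace = TRUE))
        ltr$kind <- "LTR"
        ltr$id <- sprintf("%s_LTR%03d", chroms[i], seq_along(take))
        gr <- c(gr, ltr)
      }
    }
    featList[[i]] <- gr
  }
  feats <- .concatGR(featList, si)
  cens <- .concatGR(cenList, si)
  conv <- .concatGR(convList, si)
  genome <- new("GenomeAnnotation", seqinfo = si, centromeres = cens,
                features = GenomicRanges::sort(feats, ignore.strand = TRUE))
  list(genome = genome, truth = list(convergent = conv, seed = seed))
}

#' Plant enrichment peaks under a placement regime
#'
#' Regimes mirror the observed binding patterns: \code{wildtype} draws
#' peaks from convergent intergenic sites with sampling weight
#' \code{centromereWeight} for sites inside the pericentromeric windows
#' (strong clustering); \code{top2} uses the milder \code{armWeight} so
#' sites also spread along arms; \code{cohesin_mutant} retains signal at
#' core centromeres only; \code{uniform} places peaks uniformly over the
#' genome (the null used for calibration). Sticky-artifact sites, present
#' in every immunoprecipitated sample including the no-tag control, are
#' appended with \code{kind = "sticky"}.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param regime one of \code{"wildtype"}, \code{"top2"},
#'   \code{"cohesin_mutant"}, \code{"uniform"}.
#' @param nPeaks number of peaks to plant (default \code{config$nPeaks}).
#' @param config list from \code{\link{simulationConfig}}.
#' @param seed overrides \code{config$seed + 1}.
#' @return \code{GRanges} truth set with metadata columns \code{fold},
#'   \code{kind} (\code{"peak"}/\code{"sticky"}) and
#'   \code{pericentromeric}.
#' @export
plantRegime <- function(genome, regime = c("wildtype", "top2",
                                           "cohesin_mutant", "uniform"),
                        nPeaks = config$nPeaks,
                        config = simulationConfig(),
                        seed = config$seed + 1L) {
  regime <- match.arg(regime)
  set.seed(seed)
  lens <- chromLengths(genome)
  half <- config$peakWidth %/% 2L
  cw <- centromereWindows(genome, config$pericenWidth)
  # the hot path below works on (chrom, mid0) vectors; the GRanges is
  # assembled once at the end
  drawUniformMids <- function(n) {
    cuts <- cumsum(as.numeric(lens))
    pos <- stats::runif(n, 0, cuts[length(cuts)])
    ci <- findInterval(pos, c(0, cuts), rightmost.closed = TRUE)
    list(chr = names(lens)[ci],
         mid0 = as.integer(pmin(pmax(round(pos - c(0, cuts)[ci]), half),
                                lens[ci] - half - 1)))
  }
  if (regime %in% c("wildtype", "top2")) {
    sites <- convergentIntergenicRegions(genome)
    if (length(sites) < nPeaks)
      stop("nPeaks (", nPeaks, ") exceeds available convergent sites (",
           length(sites), ")")
    sChr <- as.character(GenomicRanges::seqnames(sites))
    sMid0 <- (GenomicRanges::start(sites) - 1L +
                GenomicRanges::end(sites)) %/% 2L
    inWin <- .midsInWindows(sChr, sMid0, cw)
    wgt <- ifelse(inWin,
                  if (regime == "wildtype") config$centromereWeight else
                    config$armWeight,
                  1)
    pick <- sample.int(length(sites), nPeaks, prob = wgt)
    chr <- sChr[pick]; mid0 <- sMid0[pick]
  } else if (regime == "cohesin_mutant") {
    cen <- genome@centromeres
    if (nPeaks > length(cen))
      stop("nPeaks (", nPeaks, ") exceeds the number of core centromeres (",
           length(cen), ")")
    pick <- sample.int(length(cen), nPeaks)
    chr <- as.character(GenomicRanges::seqnames(cen))[pick]
    mid0 <- (GenomicRanges::start(cen)[pick] - 1L +
               GenomicRanges::end(cen)[pick]) %/% 2L
  } else {                                  # uniform over the genome
    chr <- character(0); mid0 <- integer(0)
    for (tries in 1:50) {
      need <- nPeaks - length(mid0)
      if (need == 0L) break
      d <- drawUniformMids(need)
      chr <- c(chr, d$chr); mid0 <- c(mid0, d$mid0)
      # drop colliding peaks (closer than peakWidth on a chromosome)
      o <- order(chr, mid0)
      chr <- chr[o]; mid0 <- mid0[o]
      tooClose <- c(FALSE, chr[-1] == chr[-length(chr)] &
                      diff(mid0) < config$peakWidth)
      bad <- tooClose | c(tooClose[-1], FALSE)
      chr <- chr[!bad]; mid0 <- mid0[!bad]
    }
  }
  fold <- rep(config$peakFold, length(mid0))
  kind <- rep("peak", length(mid0))
  # sticky-artifact sites: uniform, shared by chip and no-tag samples
  if (config$stickySites > 0L) {
    d <- drawUniformMids(config$stickySites)
    chr <- c(chr, d$chr); mid0 <- c(mid0, d$mid0)
    fold <- c(fold, rep(config$stickyFold, config$stickySites))
    kind <- c(kind, rep("sticky", config$stickySites))
  }
  gr <- GRanges(chr, IRanges(pmax(1L, mid0 - half + 1L),
                             pmin(as.integer(lens[chr]),
                                  mid0 + (config$peakWidth - half))),
                fold = fold, kind = kind,
                pericentromeric = .midsInWindows(chr, mid0, cw))
  GenomeInfoDb::seqlevels(gr) <- names(lens)
  seqinfo(gr) <- genome@seqinfo
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  metadata(gr)$regime <- regime
  metadata(gr)$seed <- seed
  gr
}

#' Simulate aligned single-end reads for one sample
#'
#' Per-bin 5' read-start counts are Poisson with rate
#' \code{backgroundDepth * binSize / fragLength}, multiplied by the
#' planted fold inside truth intervals: peaks and sticky sites for the
#' ChIP sample, nothing for WCE, sticky sites only for the no-tag
#' control. Strands are Bernoulli(0.5); reads are clipped to chromosome
#' bounds. Deterministic under \code{seed}.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param truth truth \code{GRanges} from \code{\link{plantRegime}} (or
#'   \code{NULL} for a flat sample).
#' @param sample one of \code{"chip"}, \code{"wce"}, \code{"notag"}.
#' @param config list from \code{\link{simulationConfig}}.
#' @param seed overrides the config-derived default (distinct per sample
#'   so samples are independent).
#' @return stranded \code{GRanges} of reads.
#' @export
simulateReads <- function(genome, truth = NULL,
                          sample = c("chip", "wce", "notag"),
                          config = simulationConfig(), seed = NULL) {
  sample <- match.arg(sample)
  if (is.null(seed))
    seed <- config$seed + 10L + match(sample, c("chip", "wce", "notag"))
  set.seed(seed)
  lens <- chromLengths(genome)
  B <- as.integer(config$binSize)
  rate0 <- config$backgroundDepth * B / config$fragLength
  enr <- if (is.null(truth)) GRanges() else switch(sample,
    chip = truth,
    wce = GRanges(),
    notag = truth[truth$kind == "sticky"])
  rl <- as.integer(config$readLength)
  out <- vector("list", length(lens))
  for (ci in seq_along(lens)) {
    ch <- names(lens)[ci]
    len <- lens[[ci]]
    nb <- as.integer(ceiling(len / B))
    mult <- rep(1, nb)
    e <- enr[as.character(GenomicRanges::seqnames(enr)) == ch]
    if (length(e)) {
      for (k in seq_along(e)) {
        fb <- (GenomicRanges::start(e)[k] - 1L) %/% B + 1L
        lb <- (GenomicRanges::end(e)[k] - 1L) %/% B + 1L
        mult[fb:lb] <- pmax(mult[fb:lb], e$fold[k])
      }
    }
    counts <- stats::rpois(nb, rate0 * mult)
    tot <- sum(counts)
    if (tot == 0L) {
      out[[ci]] <- GRanges()
      next
    }
    binIdx <- rep.int(seq_len(nb), counts)
    binWidth <- pmin(binIdx * B, len) - (binIdx - 1L) * B
    p1 <- (binIdx - 1L) * B + 1L +
      as.integer(floor(stats::runif(tot) * binWidth))   # 5' position, 1-based
    neg <- stats::runif(tot) < 0.5
    s <- ifelse(neg, pmax(1L, p1 - rl + 1L), p1)
    e2 <- ifelse(neg, p1, pmin(len, p1 + rl - 1L))
    out[[ci]] <- GRanges(ch, IRanges(s, e2),
                         strand = ifelse(neg, "-", "+"))
  }
  .concatGR(out, genome@seqinfo)
}

#' Simulate per-cell separation/segregation trajectories
#'
#' Produces the tidy per-frame event table the timing classifier reads,
#' together with the generating truth per cell. Each cell's spindle
#' crosses the elongation threshold at a drawn time; chromatid separation
#' follows after a drawn delay and segregation after a drawn latency,
#' with configurable probabilities of never separating or never
#' partitioning to both compartments within the observation span.
#'
#' @param nCells number of cells.
#' @param params named list of generating parameters; defaults:
#'   \code{t0Mean = 10}, \code{t0SD = 2} (spindle elongation, min),
#'   \code{sepDelayMean = 2}, \code{sepDelaySD = 1} (min),
#'   \code{latencyMean = 1.5}, \code{latencySD = 0.75} (min),
#'   \code{pNeverSeparate = 0}, \code{pNeverSegregate = 0},
#'   \code{frameInterval = 0.5}, \code{span = 70},
#'   \code{threshold = 3.18} (um).
#' @param seed integer seed.
#' @return list with \code{frames} (per-frame table) and \code{truth}
#'   (per-cell generating values).
#' @export
simulateTrajectories <- function(nCells, params = list(), seed = 1L) {
  p <- utils::modifyList(list(t0Mean = 10, t0SD = 2,
                              sepDelayMean = 2, sepDelaySD = 1,
                              latencyMean = 1.5, latencySD = 0.75,
                              pNeverSeparate = 0, pNeverSegregate = 0,
                              frameInterval = 0.5, span = 70,
                              threshold = 3.18), params)
  set.seed(seed)
  fi <- p$frameInterval
  tGrid <- seq(0, p$span, by = fi)
  snap <- function(t) ceiling(t / fi) * fi
  framesList <- vector("list", nCells)
  truthList <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    id <- sprintf("cell%04d", i)
    t0 <- snap(max(fi, stats::rnorm(1, p$t0Mean, p$t0SD)))
    neverSep <- stats::runif(1) < p$pNeverSeparate
    neverSeg <- !neverSep && stats::runif(1) < p$pNeverSegregate
    sepT <- if (neverSep) NA_real_ else
      snap(t0 + max(fi, stats::rnorm(1, p$sepDelayMean, p$sepDelaySD)))
    segT <- if (neverSep || neverSeg) NA_real_ else
      snap(sepT + max(fi, stats::rnorm(1, p$latencyMean, p$latencySD)))
    if (!is.na(sepT) && sepT > p$span) { sepT <- NA; segT <- NA }
    if (!is.na(segT) && segT > p$span) segT <- NA
    spindle <- ifelse(tGrid < t0,
                      pmin(p$threshold - 0.1,
                           1.5 + stats::runif(length(tGrid), -0.3, 0.3)),
                      pmin(8, 3.5 + 0.5 * (tGrid - t0)))
    nDots <- ifelse(!is.na(sepT) & tGrid >= sepT, 2L, 1L)
    comp <- rep("mother", length(tGrid))
    if (!is.na(segT)) comp[tGrid >= segT] <- "both"
    framesList[[i]] <- data.frame(cell_id = id, t_min = tGrid,
                                  spindle_um = round(spindle, 3),
                                  n_dots = nDots, compartment = comp,
                                  stringsAsFactors = FALSE)
    truthList[[i]] <- data.frame(cell_id = id, t0 = t0, sepTime = sepT,
                                 segTime = segT,
                                 missegregated = is.na(segT),
                                 stringsAsFactors = FALSE)
  }
  list(frames = do.call(rbind, framesList),
       truth = do.call(rbind, truthList))
}

#' Build a PeakSet directly from a planted truth set
#'
#' Convenience for spatial statistics on the generator's truth without
#' running the read-level pipeline (sticky sites are excluded).
#'
#' @param truth \code{GRanges} from \code{\link{plantRegime}}.
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param sample sample label.
#' @return a \linkS4class{PeakSet}.
#' @export
peakSetFromTruth <- function(truth, genome, sample = "truth") {
  pk <- truth[truth$kind == "peak"]
  pk <- granges(pk)
  pk$maxFE <- rep(NA_real_, length(pk))
  pk$maxChip <- rep(NA_real_, length(pk))
  pk$maxNotagFE <- rep(NA_real_, length(pk))
  GenomeInfoDb::seqlevels(pk) <- names(chromLengths(genome))
  seqinfo(pk) <- genome@seqinfo
  new("PeakSet", peaks = GenomicRanges::sort(pk, ignore.strand = TRUE),
      sample = sample, params = list(source = "truth"))
}
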