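# The three-criterion, no-tag-controlled peak caller and peak annotation.

#' Call enrichment peaks with three fixed-threshold criteria
#'
#' Candidate bins are those whose tagged-sample fold enrichment exceeds
#' \code{feThreshold}; maximal runs of contiguous candidate bins form
#' candidate regions. A region is reported as a peak iff (1) it is a
#' candidate run, (2) the maximum normalized ChIP depth over the region
#' exceeds \code{intensityFloor}, and (3) the maximum no-tag fold
#' enrichment over the region stays below \code{notagCeiling} (the
#' false-positive filter), and the region is at least \code{minWidth} bp
#' wide. With \code{mode = "bin"} criteria (2) and (3) are instead applied
#' per bin before runs are formed.
#'
#' @param feTag \linkS4class{EnrichmentTrack} of the tagged sample
#'   (ChIP/WCE).
#' @param chip normalized ChIP depth \linkS4class{BinnedTrack} (criterion 2).
#' @param feNotag \linkS4class{EnrichmentTrack} of the no-tag control, or
#'   \code{NULL} to skip criterion 3 (a warning is emitted).
#' @param feThreshold fold-enrichment threshold, exclusive (default 2.0).
#' @param intensityFloor minimum max ChIP depth, exclusive (default 1.0).
#' @param notagCeiling maximum no-tag fold enrichment, exclusive
#'   (default 1.8).
#' @param minWidth minimum peak width in bp (default 30, i.e. 3 bins at
#'   10-bp binning).
#' @param mode \code{"region"} (default): criteria 2-3 on the region
#'   maximum; \code{"bin"}: per bin.
#' @param intensityRelative if \code{TRUE}, \code{intensityFloor} is
#'   expressed relative to the genome-mean ChIP bin value instead of as an
#'   absolute depth. Useful when depth normalization has rescaled values
#'   far from per-bp units on long genomes.
#' @return a \linkS4class{PeakSet}.
#' @export
callPeaks <- function(feTag, chip, feNotag = NULL, feThreshold = 2.0,
                      intensityFloor = 1.0, notagCeiling = 1.8,
                      minWidth = 30, mode = c("region", "bin"),
                      intensityRelative = FALSE) {
  stopifnot(is(feTag, "EnrichmentTrack"), is(chip, "BinnedTrack"))
  mode <- match.arg(mode)
  .checkSameBinning(feTag, chip)
  if (is.null(feNotag)) {
    warning("no no-tag track supplied: false-positive criterion (3) skipped")
  } else {
    stopifnot(is(feNotag, "EnrichmentTrack"))
    .checkSameBinning(feTag, feNotag)
  }
  B <- feTag@binSize
  lens <- seqlengths(feTag@seqinfo)
  floorVal <- intensityFloor
  if (intensityRelative) {
    mu <- mean(unlist(chip@values, use.names = FALSE))
    floorVal <- intensityFloor * mu
  }
  out <- list()
  for (ch in names(lens)) {
    fe <- feTag@values[[ch]]
    cv <- chip@values[[ch]]
    nt <- if (is.null(feNotag)) NULL else feNotag@values[[ch]]
    cand <- fe > feThreshold
    if (mode == "bin") {
      cand <- cand & cv > floorVal
      if (!is.null(nt)) cand <- cand & nt < notagCeiling
    }
    if (!any(cand)) next
    r <- rle(cand)
    endsBin <- cumsum(r$lengths)
    startsBin <- endsBin - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep) == 0L) next
    sb <- startsBin[keep]; eb <- endsBin[keep]
    startBp <- (sb - 1L) * B + 1L
    endBp <- pmin(eb * B, lens[[ch]])
    maxFE <- vapply(seq_along(sb), function(j) max(fe[sb[j]:eb[j]]), 0)
    maxChip <- vapply(seq_along(sb), function(j) max(cv[sb[j]:eb[j]]), 0)
    maxNotag <- if (is.null(nt)) rep(NA_real_, length(sb)) else
      vapply(seq_along(sb), function(j) max(nt[sb[j]:eb[j]]), 0)
    ok <- (endBp - startBp + 1L) >= minWidth
    if (mode == "region") {
      ok <- ok & maxChip > floorVal
      if (!is.null(nt)) ok <- ok & maxNotag < notagCeiling
    }
    if (!any(ok)) next
    gr <- GRanges(ch, IRanges(startBp[ok], endBp[ok]),
                  maxFE = maxFE[ok], maxChip = maxChip[ok],
                  maxNotagFE = maxNotag[ok])
    out[[ch]] <- gr
  }
  pk <- .concatGR(out, feTag@seqinfo)
  if (length(pk) == 0L) {
    pk$maxFE <- numeric(0); pk$maxChip <- numeric(0)
    pk$maxNotagFE <- numeric(0)
  }
  pk <- GenomicRanges::sort(pk, ignore.strand = TRUE)
  new("PeakSet", peaks = pk, sample = feTag@sample,
      params = list(feThreshold = feThreshold,
                    intensityFloor = intensityFloor,
                    notagCeiling = notagCeiling, minWidth = minWidth,
                    mode = mode, notagUsed = !is.null(feNotag)))
}

#' Annotate peaks with genomic-location flags
#'
#' Each peak is assigned by its midpoint: \code{pericentromeric} if the
#' midpoint falls inside the fixed-width centromere window,
#' \code{convergentIntergenic} if inside a convergent-gene intergenic
#' region, and \code{onArm} if inside the masked chromosome-arm regions.
#' The distance from the peak midpoint to the centromere midpoint is
#' recorded as \code{distToCen}.
#'
#' @param peakSet a \linkS4class{PeakSet}.
#' @param genome a \linkS4class{GenomeAnnotation} with centromeres.
#' @param pericenWidth centromere-window width in bp (default 25000).
#' @param pericen,subtel arm-masking widths passed to
#'   \code{\link{armRegions}}.
#' @return the \linkS4class{PeakSet} with flag columns added.
#' @export
annotatePeaks <- function(peakSet, genome, pericenWidth = 25000,
                          pericen = 25000, subtel = 20000) {
  stopifnot(is(peakSet, "PeakSet"), is(genome, "GenomeAnnotation"))
  pk <- peakSet@peaks
  if (length(pk) == 0L) {
    pk$pericentromeric <- logical(0)
    pk$convergentIntergenic <- logical(0)
    pk$onArm <- logical(0)
    pk$distToCen <- numeric(0)
    return(new("PeakSet", peaks = pk, sample = peakSet@sample,
               params = c(peakSet@params, list(pericenWidth = pericenWidth))))
  }
  mid0 <- (GenomicRanges::start(pk) - 1L + GenomicRanges::end(pk)) %/% 2L
  mids <- GRanges(GenomicRanges::seqnames(pk), IRanges(mid0 + 1L, mid0 + 1L))
  GenomeInfoDb::seqlevels(mids) <- GenomeInfoDb::seqlevels(pk)
  seqinfo(mids) <- seqinfo(pk)
  cw <- centromereWindows(genome, pericenWidth)
  conv <- convergentIntergenicRegions(genome)
  arms <- armRegions(genome, pericen = pericen, subtel = subtel)
  pk$pericentromeric <- IRanges::overlapsAny(mids, cw, ignore.strand = TRUE)
  pk$convergentIntergenic <- IRanges::overlapsAny(mids, conv,
                                                  ignore.strand = TRUE)
  pk$onArm <- IRanges::overlapsAny(mids, arms, ignore.strand = TRUE)
  cenMids <- .cenMid(genome)
  chr <- as.character(GenomicRanges::seqnames(pk))
  pk$distToCen <- ifelse(chr %in% names(cenMids),
                         abs(mid0 - cenMids[chr]), NA_real_)
  new("PeakSet", peaks = pk, sample = peakSet@sample,
      params = c(peakSet@params, list(pericenWidth = pericenWidth)))
}

#' Overlap summary between two peak sets
#'
#' Counts peaks of each set (optionally restricted to a region set),
#' how many peaks of one set share at least 1 bp with a peak of the
#' other, and the Jaccard index of overlapped bp.
#'
#' @param a,b \linkS4class{PeakSet}s.
#' @param restrictTo optional \code{GRanges}; only peaks overlapping it
#'   are considered (e.g. chromosome arms from \code{\link{armRegions}}).
#' @return a list with elements \code{nA}, \code{nB}, \code{aInB},
#'   \code{bInA}, \code{fracA}, \code{fracB}, \code{jaccard},
#'   \code{overlapBp}, \code{unionBp}.
#' @export
overlapPeaks <- function(a, b, restrictTo = NULL) {
  stopifnot(is(a, "PeakSet"), is(b, "PeakSet"))
  ga <- a@peaks; gb <- b@peaks
  if (!is.null(restrictTo)) {
    ga <- ga[IRanges::overlapsAny(ga, restrictTo, ignore.strand = TRUE)]
    gb <- gb[IRanges::overlapsAny(gb, restrictTo, ignore.strand = TRUE)]
  }
  aInB <- sum(IRanges::overlapsAny(ga, gb, ignore.strand = TRUE))
  bInA <- sum(IRanges::overlapsAny(gb, ga, ignore.strand = TRUE))
  inter <- GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)
  uni <- GenomicRanges::union(ga, gb, ignore.strand = TRUE)
  ovBp <- sum(as.numeric(GenomicRanges::width(inter)))
  unBp <- sum(as.numeric(GenomicRanges::width(uni)))
  list(nA = length(ga), nB = length(gb), aInB = aInB, bInA = bInA,
       fracA = if (length(ga)) aInB / length(ga) else NA_real_,
       fracB = if (length(gb)) bInA / length(gb) else NA_real_,
       jaccard = if (unBp > 0) ovBp / unBp else NA_real_,
       overlapBp = ovBp, unionBp = unBp)
}

#' Write a PeakSet as BED6+ (extra statistic and flag columns)
#'
#' Columns 1-6 are standard BED (score = maxFE); extra columns are
#' \code{maxFE}, \code{maxChip}, \code{maxNotagFE} and, when present,
#' the annotation flags.
#'
#' @param peakSet a \linkS4class{PeakSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePeaks <- function(peakSet, path) {
  stopifnot(is(peakSet, "PeakSet"))
  pk <- peakSet@peaks
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(pk)),
    start = GenomicRanges::start(pk) - 1L,
    end = GenomicRanges::end(pk),
    name = if (length(pk)) sprintf("peak_%04d", seq_along(pk)) else character(0),
    score = round(pk$maxFE, 4),
    strand = rep(".", length(pk)),
    maxFE = pk$maxFE, maxChip = pk$maxChip, maxNotagFE = pk$maxNotagFE,
    stringsAsFactors = FALSE)
  for (fl in c("pericentromeric", "convergentIntergenic", "onArm"))
    if (!is.null(mcols(pk)[[fl]])) df[[fl]] <- as.integer(mcols(pk)[[fl]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+ peak file written by \code{\link{writePeaks}}
#'
#' @param path peak BED path.
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param sample sample label.
#' @return a \linkS4class{PeakSet}.
#' @export
readPeaks <- function(path, genome, sample = NA_character_) {
  stopifnot(is(genome, "GenomeAnnotation"))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand",
            "maxFE", "maxChip", "maxNotagFE")
  flags <- c("pericentromeric", "convergentIntergenic", "onArm")
  names(df) <- c(base, flags)[seq_len(ncol(df))]
  pk <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                maxFE = df$maxFE, maxChip = df$maxChip,
                maxNotagFE = df$maxNotagFE)
  for (fl in flags) if (!is.null(df[[fl]])) mcols(pk)[[fl]] <- df[[fl]] == 1L
  GenomeInfoDb::seqlevels(pk) <- names(chromLengths(genome))
  seqinfo(pk) <- genome@seqinfo
  new("PeakSet", peaks = GenomicRanges::sort(pk, ignore.strand = TRUE),
      sample = sample)
}
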