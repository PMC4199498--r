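# Read extension, binned coverage, normalization, smoothing and
# ChIP/WCE fold enrichment.

#' Extend aligned reads to predicted fragment length
#'
#' Each single-end read is extended to \code{fragLength} bp from its 5'
#' end in the read's orientation (downstream for \code{+} reads,
#' upstream for \code{-} reads) and clipped to the chromosome bounds.
#'
#' @param reads \code{GRanges} of aligned reads with strand
#'   (see \code{\link{readReadsBed}}).
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param fragLength predicted fragment length in bp (default 150).
#' @return unstranded \code{GRanges} of fragment intervals.
#' @export
extendReads <- function(reads, genome, fragLength = 150) {
  stopifnot(is(genome, "GenomeAnnotation"), fragLength > 0)
  if (any(!as.character(GenomicRanges::strand(reads)) %in% c("+", "-")))
    stop("reads must be stranded (+/-)")
  gr <- reads
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome@seqinfo)
  seqinfo(gr) <- genome@seqinfo
  ext <- suppressWarnings(
    GenomicRanges::resize(gr, width = as.integer(fragLength), fix = "start"))
  ext <- GenomicRanges::trim(ext)
  GenomicRanges::strand(ext) <- "*"
  ext
}

.binBounds <- function(len, binSize) {
  starts <- seq.int(1L, len, by = binSize)
  list(starts = starts, ends = pmin(starts + binSize - 1L, len))
}

#' Bin fragment coverage along the genome
#'
#' The value of each bin is the number of fragment-bp overlapping the bin
#' divided by the bin size (mean per-bp depth). Before normalization,
#' \code{sum(values) * binSize} equals the total fragment-bp, exactly.
#'
#' @param fragments unstranded \code{GRanges} of fragment intervals
#'   (from \code{\link{extendReads}}).
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param binSize bin width in bp (default 10).
#' @param sample sample label stored in the track.
#' @return a \linkS4class{BinnedTrack} (unnormalized, unsmoothed).
#' @export
binCoverage <- function(fragments, genome, binSize = 10,
                        sample = NA_character_) {
  stopifnot(is(genome, "GenomeAnnotation"), binSize > 0)
  binSize <- as.integer(binSize)
  lens <- chromLengths(genome)
  chr <- as.character(GenomicRanges::seqnames(fragments))
  vals <- vector("list", length(lens))
  names(vals) <- names(lens)
  for (ch in names(lens)) {
    len <- lens[[ch]]
    f <- fragments[chr == ch]
    bb <- .binBounds(len, binSize)
    if (length(f) == 0L) {
      vals[[ch]] <- numeric(length(bb$starts))
      next
    }
    cov <- IRanges::coverage(IRanges::ranges(f), width = len)
    v <- IRanges::viewSums(IRanges::Views(cov, start = bb$starts,
                                          end = bb$ends))
    vals[[ch]] <- as.numeric(v) / binSize
  }
  .newTrack(vals, binSize, genome@seqinfo, sample = sample)
}

#' Normalize a coverage track to a fixed total depth
#'
#' Scales all bin values so that \code{sum(values) * binSize} over the
#' whole genome equals \code{target} (default 1e6 fragment-bp), and sets
#' the normalized flag. Normalizing twice, or normalizing an all-zero
#' track, is an error.
#'
#' @param track an unnormalized \linkS4class{BinnedTrack}.
#' @param target total fragment-bp after scaling (default \code{1e6}).
#' @return the normalized track.
#' @export
normalizeDepth <- function(track, target = 1e6) {
  stopifnot(is(track, "BinnedTrack"), target > 0)
  if (track@normalized) stop("track is already normalized")
  tot <- sum(vapply(track@values, sum, 0)) * track@binSize
  if (tot == 0) stop("cannot normalize an all-zero track")
  sc <- target / tot
  vals <- lapply(track@values, function(v) v * sc)
  .newTrack(vals, track@binSize, track@seqinfo, sample = track@sample,
            normalized = TRUE, smoothed = track@smoothed,
            class = class(track))
}

.smoothVec <- function(x, h) {
  n <- length(x)
  if (h == 0L || n == 1L) return(x)
  i <- seq_len(n)
  hi <- pmin(h, i - 1L, n - i)        # symmetric shrink at the ends
  cs <- c(0, cumsum(x))
  (cs[i + hi + 1L] - cs[i - hi]) / (2 * hi + 1)
}

#' Smooth a track with a centered moving average
#'
#' The averaging window shrinks symmetrically at chromosome ends so the
#' estimate remains centered; \code{windowBins = 1} is the identity.
#'
#' @param track a \linkS4class{BinnedTrack}.
#' @param windowBins odd window width in bins (default 35, i.e. 350 bp at
#'   10-bp bins).
#' @return the smoothed track.
#' @export
smoothTrack <- function(track, windowBins = 35) {
  stopifnot(is(track, "BinnedTrack"))
  windowBins <- as.integer(windowBins)
  if (windowBins < 1L || windowBins %% 2L == 0L)
    stop("windowBins must be an odd integer >= 1")
  h <- (windowBins - 1L) %/% 2L
  vals <- lapply(track@values, .smoothVec, h = h)
  .newTrack(vals, track@binSize, track@seqinfo, sample = track@sample,
            normalized = track@normalized, smoothed = windowBins > 1L,
            class = class(track))
}

#' Per-bin ChIP/WCE fold enrichment
#'
#' \code{FE(b) = (chip(b) + pseudocount) / (wce(b) + pseudocount)}. Both
#' tracks must share binning and both must be depth-normalized; the
#' pseudocount guards against zero-coverage WCE bins.
#'
#' @param chip normalized ChIP \linkS4class{BinnedTrack}.
#' @param wce normalized whole-cell-extract (input) track.
#' @param pseudocount added to numerator and denominator (default 0.1).
#' @return an \linkS4class{EnrichmentTrack}.
#' @export
foldEnrichment <- function(chip, wce, pseudocount = 0.1) {
  stopifnot(is(chip, "BinnedTrack"), is(wce, "BinnedTrack"),
            pseudocount >= 0)
  .checkSameBinning(chip, wce)
  if (!chip@normalized || !wce@normalized)
    stop("both tracks must be depth-normalized before fold enrichment")
  vals <- lapply(names(chip@values), function(ch)
    (chip@values[[ch]] + pseudocount) / (wce@values[[ch]] + pseudocount))
  names(vals) <- names(chip@values)
  .newTrack(vals, chip@binSize, chip@seqinfo, sample = chip@sample,
            normalized = TRUE, smoothed = chip@smoothed || wce@smoothed,
            class = "EnrichmentTrack")
}

#' Export a track as bedGraph
#'
#' Writes one 4-column bedGraph line per bin (0-based half-open, as the
#' format requires).
#'
#' @param track a \linkS4class{BinnedTrack}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTrack <- function(track, path) {
  stopifnot(is(track, "BinnedTrack"))
  lens <- seqlengths(track@seqinfo)
  grl <- lapply(names(track@values), function(ch) {
    bb <- .binBounds(lens[[ch]], track@binSize)
    GRanges(ch, IRanges(bb$starts, bb$ends), score = track@values[[ch]])
  })
  gr <- .concatGR(grl, track@seqinfo)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Import a bedGraph file as a track
#'
#' The bedGraph must tile each chromosome in fixed-width bins matching
#' \code{binSize}; flags (normalized/smoothed) are supplied by the caller
#' since bedGraph carries no metadata.
#'
#' @param path bedGraph path.
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param binSize bin width in bp.
#' @param sample sample label.
#' @param normalized,smoothed track state flags.
#' @param enrichment return an \linkS4class{EnrichmentTrack} instead of a
#'   \linkS4class{BinnedTrack}.
#' @return the track.
#' @export
readTrack <- function(path, genome, binSize = 10, sample = NA_character_,
                      normalized = FALSE, smoothed = FALSE,
                      enrichment = FALSE) {
  stopifnot(is(genome, "GenomeAnnotation"))
  binSize <- as.integer(binSize)
  gr <- rtracklayer::import(path, format = "bedGraph")
  lens <- chromLengths(genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  vals <- vector("list", length(lens))
  names(vals) <- names(lens)
  for (ch in names(lens)) {
    nb <- as.integer(ceiling(lens[[ch]] / binSize))
    v <- numeric(nb)
    g <- gr[chr == ch]
    if (length(g)) {
      idx <- (GenomicRanges::start(g) - 1L) %/% binSize + 1L
      v[idx] <- g$score
    }
    vals[[ch]] <- v
  }
  .newTrack(vals, binSize, genome@seqinfo, sample = sample,
            normalized = normalized, smoothed = smoothed,
            class = if (enrichment) "EnrichmentTrack" else "BinnedTrack")
}
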