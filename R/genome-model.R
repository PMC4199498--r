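# Region algebra around centromeres, chromosome arms, and convergent genes.
# All widths are bp; intervals are returned as GRanges on the genome's
# Seqinfo.

.cenMid <- function(genome, chrom = NULL) {
  cen <- genome@centromeres
  if (!is.null(chrom)) {
    cen <- cen[as.character(GenomicRanges::seqnames(cen)) == chrom]
    if (length(cen) == 0L) stop("no centromere for chromosome: ", chrom)
  }
  # midpoint in 0-based coordinates: floor((start0 + end0) / 2)
  mids <- (GenomicRanges::start(cen) - 1L + GenomicRanges::end(cen)) %/% 2L
  stats::setNames(mids, as.character(GenomicRanges::seqnames(cen)))
}

.windowAroundMid <- function(mid0, width, len, chrom, si, side) {
  half <- width %/% 2L
  bounds <- switch(side,
    center = c(mid0 - half, mid0 + (width - half)),
    left   = c(mid0 - width, mid0),
    right  = c(mid0, mid0 + width))
  s0 <- max(0, bounds[1]); e0 <- min(len, bounds[2])
  if (e0 <= s0) return(GRanges(seqinfo = si))
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
  seqinfo(gr) <- si
  gr
}

#' Fixed-width window spanning (or flanking) a centromere
#'
#' Returns the interval of at most \code{width} bp centered on the
#' centromere midpoint (\code{side = "center"}), or the flank of
#' \code{width} bp immediately to the left or right of the midpoint,
#' truncated at the chromosome ends.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param chrom chromosome name.
#' @param width window width in bp (e.g. 25000 for masking/clustering,
#'   100000 for enrichment scoring, 50000 for per-arm flanks).
#' @param side \code{"center"} (default), \code{"left"} or \code{"right"}.
#' @return a \code{GRanges} of length 1 (or 0 if fully truncated).
#' @export
centromereWindow <- function(genome, chrom, width,
                             side = c("center", "left", "right")) {
  stopifnot(is(genome, "GenomeAnnotation"), width > 0)
  side <- match.arg(side)
  lens <- chromLengths(genome)
  if (!chrom %in% names(lens)) stop("unknown chromosome: ", chrom)
  mid0 <- .cenMid(genome, chrom)
  .windowAroundMid(mid0, as.integer(width), lens[[chrom]], chrom,
                   genome@seqinfo, side)
}

#' Centromere windows for every chromosome
#'
#' @inheritParams centromereWindow
#' @return \code{GRanges}, one window per chromosome with a centromere
#'   (empty windows dropped).
#' @export
centromereWindows <- function(genome, width,
                              side = c("center", "left", "right")) {
  stopifnot(is(genome, "GenomeAnnotation"), width > 0)
  side <- match.arg(side)
  width <- as.integer(width)
  mids <- .cenMid(genome)
  lens <- chromLengths(genome)[names(mids)]
  half <- width %/% 2L
  s0 <- switch(side, center = mids - half, left = mids - width,
               right = mids)
  e0 <- switch(side, center = mids + (width - half), left = mids,
               right = mids + width)
  s0 <- pmax(0, s0); e0 <- pmin(lens, e0)
  keep <- e0 > s0
  out <- GRanges(names(mids)[keep], IRanges(s0[keep] + 1L, e0[keep]))
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(genome@seqinfo)
  seqinfo(out) <- genome@seqinfo
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Shortest-arm length of a chromosome
#'
#' Distance from the centromere midpoint to the nearest telomere: the
#' length of the shorter chromosome arm.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param chrom chromosome name.
#' @return length in bp.
#' @export
shortestArmLength <- function(genome, chrom) {
  lens <- chromLengths(genome)
  if (!chrom %in% names(lens)) stop("unknown chromosome: ", chrom)
  mid0 <- .cenMid(genome, chrom)
  min(mid0, lens[[chrom]] - mid0)
}

#' Shortest-arm lengths for all chromosomes
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return named numeric vector, bp per chromosome.
#' @export
shortestArmLengths <- function(genome) {
  chroms <- as.character(GenomicRanges::seqnames(genome@centromeres))
  stats::setNames(vapply(chroms, function(ch)
    shortestArmLength(genome, ch), 0), chroms)
}

#' Left/right arm lengths for all chromosomes
#'
#' Arm lengths are measured from the telomere to the centromere midpoint.
#' Names are \code{"<chrom>:left"} and \code{"<chrom>:right"}, matching the
#' naming used by \code{\link{pericentromericEnrichment}} with
#' \code{side = "arms"}.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return named numeric vector of arm lengths in bp.
#' @export
armLengths <- function(genome) {
  lens <- chromLengths(genome)
  mids <- .cenMid(genome)
  chroms <- names(mids)
  out <- c(stats::setNames(mids, paste0(chroms, ":left")),
           stats::setNames(lens[chroms] - mids, paste0(chroms, ":right")))
  out[order(names(out))]
}

# LTR exclusion zones: each LTR is extended to the end of the nearest
# upstream ORF and the start of the nearest downstream ORF; with no
# flanking ORF on a side, to the chromosome end on that side.
.ltrExclusions <- function(genome) {
  ltrs <- features(genome, "LTR")
  if (length(ltrs) == 0L) return(GRanges(seqinfo = genome@seqinfo))
  gn <- genes(genome)
  lens <- chromLengths(genome)
  res <- vector("list", length(ltrs))
  lchr <- as.character(GenomicRanges::seqnames(ltrs))
  gchr <- as.character(GenomicRanges::seqnames(gn))
  for (i in seq_along(ltrs)) {
    ch <- lchr[i]
    g <- gn[gchr == ch]
    ls0 <- GenomicRanges::start(ltrs)[i] - 1L
    le0 <- GenomicRanges::end(ltrs)[i]
    ge0 <- GenomicRanges::end(g)
    gs0 <- GenomicRanges::start(g) - 1L
    upEnds <- ge0[ge0 <= ls0]
    dnStarts <- gs0[gs0 >= le0]
    s0 <- if (length(upEnds)) max(upEnds) else 0L
    e0 <- if (length(dnStarts)) min(dnStarts) else lens[[ch]]
    res[[i]] <- GRanges(ch, IRanges(s0 + 1L, e0))
  }
  out <- .concatGR(res, genome@seqinfo)
  reduce(GenomicRanges::sort(out, ignore.strand = TRUE))
}

#' Chromosome-arm regions after masking
#'
#' Arms are the whole chromosomes minus three exclusion classes: a
#' pericentromeric window of \code{pericen} bp spanning each centromere
#' midpoint, subtelomeric zones of \code{subtel} bp proximal to each
#' telomere, and LTR zones extended from the nearest upstream ORF end to
#' the nearest downstream ORF start around each LTR.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param pericen pericentromeric exclusion width in bp (default 25000).
#' @param subtel subtelomeric exclusion width in bp per telomere
#'   (default 20000).
#' @return sorted, disjoint \code{GRanges} of arm regions (possibly empty
#'   for chromosomes shorter than the combined exclusions).
#' @export
armRegions <- function(genome, pericen = 25000, subtel = 20000) {
  stopifnot(is(genome, "GenomeAnnotation"), pericen >= 0, subtel >= 0)
  lens <- chromLengths(genome)
  whole <- GRanges(names(lens), IRanges(1L, unname(lens)))
  GenomeInfoDb::seqlevels(whole) <- names(lens)
  seqinfo(whole) <- genome@seqinfo
  excl <- list()
  if (pericen > 0)
    excl$cen <- centromereWindows(genome, pericen, side = "center")
  if (subtel > 0) {
    st <- c(GRanges(names(lens), IRanges(1L, pmin(unname(lens),
                                                  as.integer(subtel)))),
            GRanges(names(lens),
                    IRanges(pmax(1L, unname(lens) - as.integer(subtel) + 1L),
                            unname(lens))))
    GenomeInfoDb::seqlevels(st) <- names(lens)
    seqinfo(st) <- genome@seqinfo
    excl$subtel <- st
  }
  excl$ltr <- .ltrExclusions(genome)
  excl <- excl[vapply(excl, length, 1L) > 0]
  if (length(excl) == 0L) return(GenomicRanges::sort(whole))
  mask <- reduce(GenomicRanges::sort(do.call(c, unname(excl)),
                                     ignore.strand = TRUE))
  GenomicRanges::setdiff(whole, mask, ignore.strand = TRUE)
}

#' Intergenic regions between convergently transcribed genes
#'
#' For every pair of strictly adjacent genes oriented \code{+} then
#' \code{-} (head-to-head at their 3' ends), the intergenic interval from
#' the \code{+} gene's end to the \code{-} gene's start. Overlapping or
#' nested genes break adjacency; non-positive gaps are dropped, so the
#' returned regions never overlap a gene body.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return sorted \code{GRanges} of convergent intergenic regions.
#' @export
convergentIntergenicRegions <- function(genome) {
  stopifnot(is(genome, "GenomeAnnotation"))
  gn <- genes(genome)
  lens <- chromLengths(genome)
  if (length(gn) == 0L) return(GRanges(seqinfo = genome@seqinfo))
  gn <- GenomicRanges::sort(gn, ignore.strand = TRUE)
  chr <- as.character(GenomicRanges::seqnames(gn))
  res <- list()
  for (ch in unique(chr)) {
    g <- gn[chr == ch]
    if (length(g) < 2L) next
    e0 <- GenomicRanges::end(g)
    s0 <- GenomicRanges::start(g) - 1L
    st <- as.character(GenomicRanges::strand(g))
    n <- length(g)
    i <- seq_len(n - 1L)
    # gene i must not be contained in / overtopped by an earlier gene
    clearUpstream <- e0[i] >= cummax(e0)[i]
    conv <- st[i] == "+" & st[i + 1L] == "-"
    gap <- s0[i + 1L] - e0[i] > 0L
    keep <- which(clearUpstream & conv & gap)
    if (length(keep))
      res[[ch]] <- GRanges(ch, IRanges(e0[keep] + 1L, s0[keep + 1L]))
  }
  if (length(res) == 0L) return(GRanges(seqinfo = genome@seqinfo))
  out <- .concatGR(res, genome@seqinfo)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}
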