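#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomeInfoDb
#' @import GenomicRanges
NULL

#' GenomeAnnotation: chromosomes, centromeres and features of a yeast genome
#'
#' Container for the coordinate model the ChIP-seq analysis runs against:
#' chromosome lengths (a \link[GenomeInfoDb]{Seqinfo}), one centromere
#' interval per chromosome, and strand-annotated features (genes, LTRs,
#' ARS elements).
#'
#' @slot seqinfo \code{Seqinfo} with chromosome names and lengths.
#' @slot centromeres \code{GRanges}, exactly one range per chromosome.
#' @slot features \code{GRanges} with metadata columns \code{kind}
#'   (\code{"gene"}, \code{"LTR"}, \code{"ARS"} or \code{"other"}) and
#'   \code{id}; genes carry strand \code{+} or \code{-}.
#'
#' @aliases GenomeAnnotation-class
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(
    seqinfo = "Seqinfo",
    centromeres = "GRanges",
    features = "GRanges"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msgs <- character(0)
  si <- object@seqinfo
  lens <- seqlengths(si)
  if (length(lens) == 0L) msgs <- c(msgs, "no chromosomes")
  if (anyDuplicated(names(lens)))
    msgs <- c(msgs, "chromosome names must be unique")
  if (any(is.na(lens)) || any(lens <= 0))
    msgs <- c(msgs, "chromosome lengths must be positive")
  checkBounds <- function(gr, what) {
    if (length(gr) == 0L) return(character(0))
    chr <- as.character(seqnames(gr))
    bad <- !(chr %in% names(lens))
    if (any(bad))
      return(sprintf("%s on unknown chromosome: %s", what,
                     paste(unique(chr[bad]), collapse = ", ")))
    out <- start(gr) < 1L | end(gr) > lens[chr]
    if (any(out))
      return(sprintf("%s out of chromosome bounds (e.g. %s:%d-%d)", what,
                     chr[which(out)[1]], start(gr)[which(out)[1]],
                     end(gr)[which(out)[1]]))
    character(0)
  }
  msgs <- c(msgs, checkBounds(object@centromeres, "centromere"))
  msgs <- c(msgs, checkBounds(object@features, "feature"))
  cenChr <- as.character(seqnames(object@centromeres))
  if (anyDuplicated(cenChr))
    msgs <- c(msgs, "more than one centromere on a chromosome")
  if (length(object@features) > 0L) {
    kind <- object@features$kind
    if (is.null(kind))
      msgs <- c(msgs, "features need a 'kind' metadata column")
    else {
      g <- kind == "gene"
      if (any(g) && any(!as.character(strand(object@features)[g]) %in%
                          c("+", "-")))
        msgs <- c(msgs, "genes must be stranded (+/-)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' BinnedTrack: fixed-width binned genome coverage
#'
#' Per-chromosome vectors of non-negative bin values at a declared bin size.
#' Values are mean per-bp fragment depth within the bin (fragment-bp
#' overlapping the bin divided by the bin size), so
#' \code{sum(values) * binSize} equals total fragment-bp before
#' normalization. The last bin of a chromosome may be physically truncated
#' but is reported like any bin.
#'
#' @slot binSize integer bin width in bp.
#' @slot values named list, one numeric vector per chromosome with
#'   \code{ceiling(length / binSize)} elements.
#' @slot seqinfo \code{Seqinfo} of the genome the track is binned on.
#' @slot sample sample label.
#' @slot normalized logical; \code{TRUE} after depth normalization.
#' @slot smoothed logical; \code{TRUE} after moving-average smoothing.
#'
#' @aliases BinnedTrack-class
#' @exportClass BinnedTrack
setClass("BinnedTrack",
  representation(
    binSize = "integer",
    values = "list",
    seqinfo = "Seqinfo",
    sample = "character",
    normalized = "logical",
    smoothed = "logical"
  ),
  prototype(sample = NA_character_, normalized = FALSE, smoothed = FALSE)
)

setValidity("BinnedTrack", function(object) {
  msgs <- character(0)
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize < 1L)
    msgs <- c(msgs, "binSize must be a single positive integer")
  lens <- seqlengths(object@seqinfo)
  if (!identical(sort(names(object@values)), sort(names(lens))))
    msgs <- c(msgs, "value list names must match chromosome names")
  else {
    for (chr in names(lens)) {
      v <- object@values[[chr]]
      nb <- as.integer(ceiling(lens[[chr]] / object@binSize))
      if (length(v) != nb) {
        msgs <- c(msgs, sprintf("chromosome %s: %d bins, expected %d",
                                chr, length(v), nb))
        next
      }
      if (any(!is.finite(v)) || any(v < 0))
        msgs <- c(msgs, sprintf("chromosome %s: values must be finite and >= 0",
                                chr))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EnrichmentTrack: per-bin ChIP/WCE fold-enrichment ratios
#'
#' A \linkS4class{BinnedTrack} whose values are fold-enrichment ratios
#' rather than depths; produced by \code{\link{foldEnrichment}}.
#'
#' @aliases EnrichmentTrack-class
#' @exportClass EnrichmentTrack
setClass("EnrichmentTrack", contains = "BinnedTrack")

#' PeakSet: called enrichment peaks with per-peak statistics
#'
#' Sorted, non-overlapping peak intervals with the statistics used by the
#' three calling criteria (\code{maxFE}, \code{maxChip}, \code{maxNotagFE})
#' and, after \code{\link{annotatePeaks}}, location flags
#' (\code{pericentromeric}, \code{convergentIntergenic}, \code{onArm},
#' \code{distToCen}).
#'
#' @slot peaks \code{GRanges} of peaks, sorted and disjoint.
#' @slot sample sample label.
#' @slot params list snapshot of the calling parameters.
#'
#' @aliases PeakSet-class
#' @exportClass PeakSet
setClass("PeakSet",
  representation(peaks = "GRanges", sample = "character", params = "list"),
  prototype(sample = NA_character_, params = list())
)

setValidity("PeakSet", function(object) {
  gr <- object@peaks
  if (length(gr) < 2L) return(TRUE)
  s <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!identical(start(s), start(gr)) ||
      !identical(as.character(seqnames(s)), as.character(seqnames(gr))))
    return("peaks must be sorted")
  if (!GenomicRanges::isDisjoint(gr, ignore.strand = TRUE))
    return("peaks must be non-overlapping")
  TRUE
})

setMethod("show", "GenomeAnnotation", function(object) {
  lens <- seqlengths(object@seqinfo)
  kinds <- if (length(object@features)) table(object@features$kind) else NULL
  cat("GenomeAnnotation:", length(lens), "chromosomes,",
      format(sum(as.numeric(lens)), big.mark = ","), "bp total\n")
  cat("  centromeres:", length(object@centromeres), "\n")
  if (!is.null(kinds))
    cat("  features:", paste(sprintf("%s=%d", names(kinds), kinds),
                             collapse = ", "), "\n")
})

setMethod("show", "BinnedTrack", function(object) {
  cat(class(object), sprintf("'%s'", object@sample), "\n")
  cat("  binSize:", object@binSize, "bp;",
      length(object@values), "chromosomes;",
      sum(vapply(object@values, length, 1L)), "bins\n")
  cat("  normalized:", object@normalized, " smoothed:", object@smoothed, "\n")
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet '", object@sample, "': ", length(object@peaks), " peaks\n",
      sep = "")
  if (length(object@params))
    cat("  params:", paste(sprintf("%s=%s", names(object@params),
                                   vapply(object@params, format, "")),
                           collapse = ", "), "\n")
})

# ---- accessors ----

#' Chromosome lengths of a GenomeAnnotation
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return named integer vector of chromosome lengths in bp.
#' @export
chromLengths <- function(genome) {
  stopifnot(is(genome, "GenomeAnnotation"))
  seqlengths(genome@seqinfo)
}

#' Centromere intervals
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return \code{GRanges} of centromeres, one per chromosome.
#' @export
centromeres <- function(genome) {
  stopifnot(is(genome, "GenomeAnnotation"))
  genome@centromeres
}

#' Annotated features, optionally filtered by kind
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param kind optional feature kind, e.g. \code{"gene"} or \code{"LTR"}.
#' @return \code{GRanges} of features.
#' @export
features <- function(genome, kind = NULL) {
  stopifnot(is(genome, "GenomeAnnotation"))
  f <- genome@features
  if (!is.null(kind)) f <- f[f$kind %in% kind]
  f
}

#' Gene features
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return \code{GRanges} of genes.
#' @export
genes <- function(genome) features(genome, "gene")

#' Per-chromosome bin values of a track
#' @param track a \linkS4class{BinnedTrack}.
#' @param chrom optional single chromosome name.
#' @return named list of numeric vectors, or one vector if \code{chrom}
#'   is given.
#' @export
trackValues <- function(track, chrom = NULL) {
  stopifnot(is(track, "BinnedTrack"))
  if (is.null(chrom)) return(track@values)
  if (!chrom %in% names(track@values))
    stop("unknown chromosome: ", chrom)
  track@values[[chrom]]
}

#' Bin size of a track
#' @param track a \linkS4class{BinnedTrack}.
#' @return integer bin size in bp.
#' @export
binSize <- function(track) {
  stopifnot(is(track, "BinnedTrack"))
  track@binSize
}

#' Peaks of a PeakSet as GRanges
#' @param x a \linkS4class{PeakSet}.
#' @return \code{GRanges} with per-peak statistics as metadata columns.
#' @export
peaks <- function(x) {
  stopifnot(is(x, "PeakSet"))
  x@peaks
}

#' Calling-parameter snapshot of a PeakSet
#' @param x a \linkS4class{PeakSet}.
#' @return named list of parameters.
#' @export
peakParams <- function(x) {
  stopifnot(is(x, "PeakSet"))
  x@params
}

# internal: shared track compatibility check
.checkSameBinning <- function(a, b) {
  if (a@binSize != b@binSize)
    stop("bin size mismatch: ", a@binSize, " vs ", b@binSize)
  la <- seqlengths(a@seqinfo); lb <- seqlengths(b@seqinfo)
  if (!identical(la[sort(names(la))], lb[sort(names(lb))]))
    stop("tracks are binned on different genomes")
  invisible(TRUE)
}

.newTrack <- function(values, binSize, seqinfo, sample = NA_character_,
                      normalized = FALSE, smoothed = FALSE,
                      class = "BinnedTrack") {
  new(class, binSize = as.integer(binSize), values = values,
      seqinfo = seqinfo, sample = as.character(sample),
      normalized = normalized, smoothed = smoothed)
}
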