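# Spatial statistics: windowed net enrichment, arm-length correlations,
# and the pericentromeric clustering test.

#' Net enrichment (tag minus no-tag) summed over windows
#'
#' For each window, sums \code{FE_tag(b) - FE_notag(b)} over the bins it
#' covers; bins only partially inside the window contribute in proportion
#' to their overlap fraction. Negative sums are reported as-is.
#'
#' @param feTag \linkS4class{EnrichmentTrack} of the tagged sample.
#' @param feNotag \linkS4class{EnrichmentTrack} of the no-tag control.
#' @param windows \code{GRanges} of scoring windows (e.g.
#'   \code{\link{centromereWindows}}).
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{net}.
#' @export
windowEnrichment <- function(feTag, feNotag, windows) {
  stopifnot(is(feTag, "EnrichmentTrack"), is(feNotag, "EnrichmentTrack"))
  .checkSameBinning(feTag, feNotag)
  B <- feTag@binSize
  chr <- as.character(GenomicRanges::seqnames(windows))
  s <- GenomicRanges::start(windows)
  e <- GenomicRanges::end(windows)
  net <- numeric(length(windows))
  for (i in seq_along(windows)) {
    d <- feTag@values[[chr[i]]] - feNotag@values[[chr[i]]]
    fb <- (s[i] - 1L) %/% B + 1L
    lb <- (e[i] - 1L) %/% B + 1L
    idx <- fb:lb
    binStart <- (idx - 1L) * B + 1L
    binEnd <- binStart + B - 1L
    w <- (pmin(binEnd, e[i]) - pmax(binStart, s[i]) + 1L) / B
    net[i] <- sum(d[idx] * w)
  }
  data.frame(chrom = chr, start = s, end = e, net = net,
             stringsAsFactors = FALSE)
}

#' Pericentromeric net enrichment per chromosome or per arm
#'
#' Convenience wrapper scoring \code{\link{windowEnrichment}} either on
#' fixed-width windows spanning each centromere (\code{side = "center"};
#' one value per chromosome, named by chromosome) or on the left/right
#' flanks of each centromere (\code{side = "arms"}; two values per
#' chromosome, named \code{"<chrom>:left"} / \code{"<chrom>:right"} to
#' match \code{\link{armLengths}}).
#'
#' @param feTag,feNotag \linkS4class{EnrichmentTrack}s.
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param width window width in bp (100000 for centromere-spanning
#'   windows; use 50000 for arm flanks).
#' @param side \code{"center"} or \code{"arms"}.
#' @return named numeric vector of net enrichment values.
#' @export
pericentromericEnrichment <- function(feTag, feNotag, genome,
                                      width = 100000,
                                      side = c("center", "arms")) {
  side <- match.arg(side)
  if (side == "center") {
    w <- centromereWindows(genome, width, side = "center")
    we <- windowEnrichment(feTag, feNotag, w)
    return(stats::setNames(we$net, we$chrom))
  }
  left <- centromereWindows(genome, width, side = "left")
  right <- centromereWindows(genome, width, side = "right")
  wl <- windowEnrichment(feTag, feNotag, left)
  wr <- windowEnrichment(feTag, feNotag, right)
  out <- c(stats::setNames(wl$net, paste0(wl$chrom, ":left")),
           stats::setNames(wr$net, paste0(wr$chrom, ":right")))
  out[order(names(out))]
}

#' Correlate net enrichment with chromosome or arm length
#'
#' Pearson (primary) and Spearman correlation between per-chromosome (or
#' per-arm) net enrichment values and a length predictor: full chromosome
#' length, arm length (unit of observation is then an arm), or
#' shortest-arm length (centromere-to-nearest-telomere distance). The
#' rDNA-bearing chromosome XII is excluded by default because its true
#' length is unknown.
#'
#' @param values named numeric vector of net enrichment; names are
#'   chromosomes, or \code{"<chrom>:left"}/\code{"<chrom>:right"} arms for
#'   \code{predictor = "arm_length"}.
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param predictor one of \code{"chrom_length"}, \code{"arm_length"},
#'   \code{"shortest_arm"}.
#' @param exclude chromosomes dropped before correlating
#'   (default \code{"chrXII"}).
#' @return a list with \code{predictor}, \code{n}, \code{pearson},
#'   \code{spearman}, \code{excluded} and the point table \code{points}.
#' @export
correlateEnrichment <- function(values, genome,
                                predictor = c("chrom_length", "arm_length",
                                              "shortest_arm"),
                                exclude = "chrXII") {
  stopifnot(is(genome, "GenomeAnnotation"), is.numeric(values),
            !is.null(names(values)))
  predictor <- match.arg(predictor)
  pred <- switch(predictor,
    chrom_length = chromLengths(genome),
    shortest_arm = shortestArmLengths(genome),
    arm_length = armLengths(genome))
  baseChrom <- sub(":(left|right)$", "", names(values))
  keep <- !(baseChrom %in% exclude)
  values <- values[keep]
  missing <- setdiff(names(values), names(pred))
  if (length(missing))
    stop("no predictor value for: ", paste(missing, collapse = ", "))
  x <- as.numeric(pred[names(values)])
  y <- as.numeric(values)
  if (length(y) < 3L) stop("fewer than 3 points after exclusion")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  list(predictor = predictor, n = length(y),
       pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       excluded = exclude,
       points = data.frame(unit = names(values), predictor = x, net = y,
                           stringsAsFactors = FALSE))
}

#' Exact binomial test for pericentromeric peak clustering
#'
#' Tests whether peaks cluster inside fixed-width centromere windows
#' against a uniform-placement null: under uniformity a peak midpoint
#' falls in a window with probability \code{p0}, the fraction of the
#' genome the windows cover. The p-value is the one-sided upper tail
#' \code{P(X >= k | n, p0)} of the exact binomial distribution (no normal
#' approximation).
#'
#' @param peakSet a \linkS4class{PeakSet} with at least one peak.
#' @param genome a \linkS4class{GenomeAnnotation} with centromeres.
#' @param pericenWidth centromere-window width in bp (default 25000).
#' @return a list with \code{nPeaks}, \code{k} (peaks with midpoint in a
#'   window), \code{p0}, and the one-sided \code{p}.
#' @export
pericentromericClusteringTest <- function(peakSet, genome,
                                          pericenWidth = 25000) {
  stopifnot(is(peakSet, "PeakSet"), is(genome, "GenomeAnnotation"))
  pk <- peakSet@peaks
  n <- length(pk)
  if (n < 1L) stop("need at least one peak")
  w <- centromereWindows(genome, pericenWidth)
  lens <- chromLengths(genome)
  p0 <- sum(as.numeric(GenomicRanges::width(w))) / sum(as.numeric(lens))
  if (p0 <= 0) stop("centromere windows cover zero genome fraction")
  p0 <- min(p0, 1)
  mid0 <- (GenomicRanges::start(pk) - 1L + GenomicRanges::end(pk)) %/% 2L
  k <- sum(.midsInWindows(as.character(GenomicRanges::seqnames(pk)),
                          mid0, w))
  p <- stats::pbinom(k - 1L, size = n, prob = p0, lower.tail = FALSE)
  list(nPeaks = n, k = k, p0 = p0, p = p)
}
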