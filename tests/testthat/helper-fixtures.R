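# Fixtures built in code: toy genomes and hand-made tracks.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# A minimal genome from explicit pieces. cenMid0 are 0-based centromere
# midpoints; genes/ltrs are data.frames with start0/end0/strand columns.
toyGenome <- function(lens, cenMid0 = NULL, genes = NULL, ltrs = NULL,
                      cenLen = 120L) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(lens),
                              seqlengths = unname(lens))
  half <- cenLen %/% 2L
  cen <- GRanges()
  if (!is.null(cenMid0)) {
    cen <- GRanges(names(cenMid0),
                   IRanges(unname(cenMid0) - half + 1L,
                           unname(cenMid0) + (cenLen - half)))
  }
  GenomeInfoDb::seqlevels(cen) <- names(lens)
  GenomeInfoDb::seqinfo(cen) <- si
  featList <- list()
  if (!is.null(genes))
    featList$genes <- GRanges(genes$chrom,
                              IRanges(genes$start0 + 1L, genes$end0),
                              strand = genes$strand, kind = "gene",
                              id = sprintf("g%03d", seq_len(nrow(genes))))
  if (!is.null(ltrs))
    featList$ltrs <- GRanges(ltrs$chrom,
                             IRanges(ltrs$start0 + 1L, ltrs$end0),
                             strand = "+", kind = "LTR",
                             id = sprintf("ltr%03d", seq_len(nrow(ltrs))))
  feats <- if (length(featList))
    suppressWarnings(do.call(c, unname(featList))) else GRanges()
  GenomeInfoDb::seqlevels(feats) <- names(lens)
  GenomeInfoDb::seqinfo(feats) <- si
  feats <- GenomicRanges::sort(feats, ignore.strand = TRUE)
  new("GenomeAnnotation", seqinfo = si, centromeres = cen,
      features = feats)
}

# Build a BinnedTrack directly from a named list of bin-value vectors.
toyTrack <- function(values, binSize, genome, normalized = FALSE,
                     smoothed = FALSE, enrichment = FALSE,
                     sample = "toy") {
  smcseq:::.newTrack(values, binSize, genome@seqinfo, sample = sample,
                     normalized = normalized, smoothed = smoothed,
                     class = if (enrichment) "EnrichmentTrack" else
                       "BinnedTrack")
}

# Independent per-bp membership oracle: which of 0-based positions
# 0..(len-1) fall inside a GRanges region set.
bpMembership <- function(gr, chrom, len) {
  inSet <- logical(len)
  g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  for (i in seq_along(g)) {
    s0 <- GenomicRanges::start(g)[i] - 1L
    e0 <- GenomicRanges::end(g)[i]
    if (e0 > s0) inSet[(s0 + 1L):e0] <- TRUE
  }
  inSet
}

# Independent brute-force caller used as the peak-calling oracle:
# literal per-bin evaluation of the three criteria with region-level
# max filters, written without run-length tricks.
bruteForceCalls <- function(fe, chip, notag, feThr = 2.0, floor = 1.0,
                            ceiling = 1.8, minBins = 3L) {
  n <- length(fe)
  cand <- fe > feThr
  regions <- list()
  i <- 1L
  while (i <= n) {
    if (!cand[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && cand[j + 1L]) j <- j + 1L
    idx <- i:j
    ok <- length(idx) >= minBins && max(chip[idx]) > floor
    if (!is.null(notag)) ok <- ok && max(notag[idx]) < ceiling
    if (ok) regions[[length(regions) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  if (length(regions) == 0L)
    return(matrix(integer(0), ncol = 2))
  do.call(rbind, regions)
}

# Frame table for one cell from event times (NA = never happens).
cellFrames <- function(id, t0, sepT = NA, segT = NA, span = 70,
                       frameInterval = 0.5, threshold = 3.18) {
  t <- seq(0, span, by = frameInterval)
  spindle <- ifelse(t < t0, 2.0, 4.0)
  nd <- ifelse(!is.na(sepT) & t >= sepT, 2L, 1L)
  comp <- rep("mother", length(t))
  if (!is.na(segT)) comp[t >= segT] <- "both"
  data.frame(cell_id = id, t_min = t, spindle_um = spindle,
             n_dots = nd, compartment = comp, stringsAsFactors = FALSE)
}
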