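# internal helpers

# Membership of 0-based midpoints in a window GRanges, computed in
# integer space (hot path: called per simulated peak set).
.midsInWindows <- function(chr, mid0, windows) {
  inw <- rep(FALSE, length(mid0))
  wchr <- as.character(GenomicRanges::seqnames(windows))
  ws0 <- GenomicRanges::start(windows) - 1L
  we0 <- GenomicRanges::end(windows)
  for (i in seq_along(windows))
    inw <- inw | (chr == wchr[i] & mid0 >= ws0[i] & mid0 < we0[i])
  inw
}

# Concatenate per-chromosome GRanges built without shared seqlevels and
# put them onto a genome's Seqinfo. The seqlevel-merge warning from c()
# is spurious here: levels are unified immediately afterwards.
.concatGR <- function(grl, si) {
  grl <- grl[vapply(grl, function(g) !is.null(g) && length(g) > 0, TRUE)]
  out <- if (length(grl)) suppressWarnings(do.call(c, unname(grl))) else
    GRanges()
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(si)
  seqinfo(out) <- si
  out
}
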