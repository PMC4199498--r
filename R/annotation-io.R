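#' Load a genome annotation from GFF3 + chromosome sizes
#'
#' Reads features from a GFF3 file and chromosome lengths from a two-column
#' (name, length) tab-separated file, and assembles a validated
#' \linkS4class{GenomeAnnotation}. GFF3 \code{type} values are mapped to
#' feature kinds: \code{gene} -> gene, \code{long_terminal_repeat} /
#' \code{LTR_retrotransposon} -> LTR, \code{ARS} /
#' \code{origin_of_replication} -> ARS, \code{centromere} -> centromere
#' (stored separately); anything else -> other.
#'
#' @param gffPath path to a GFF3 file.
#' @param chromSizesPath path to a two-column chrom-sizes TSV.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
loadAnnotation <- function(gffPath, chromSizesPath) {
  sizes <- utils::read.table(chromSizesPath, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "integer"))
  if (anyDuplicated(sizes$chrom))
    stop("duplicated chromosome in chrom-sizes file")
  si <- Seqinfo(seqnames = sizes$chrom, seqlengths = sizes$length)
  gr <- rtracklayer::import(gffPath, format = "gff3")
  chr <- as.character(GenomicRanges::seqnames(gr))
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  bad <- !(chr %in% sizes$chrom)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("feature '%s' lies on chromosome '%s' absent from chrom-sizes",
                 ifelse(is.na(ids[i]), as.character(i), ids[i]), chr[i]))
  }
  lens <- stats::setNames(sizes$length, sizes$chrom)
  out <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens[chr]
  if (any(out)) {
    i <- which(out)[1]
    stop(sprintf("feature '%s' (%s:%d-%d) exceeds chromosome bounds",
                 ifelse(is.na(ids[i]), as.character(i), ids[i]), chr[i],
                 GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
  }
  type <- as.character(gr$type)
  kind <- rep("other", length(gr))
  kind[type == "gene"] <- "gene"
  kind[type %in% c("long_terminal_repeat", "LTR_retrotransposon")] <- "LTR"
  kind[type %in% c("ARS", "origin_of_replication")] <- "ARS"
  isCen <- type == "centromere"
  cen <- granges(gr[isCen])
  GenomeInfoDb::seqlevels(cen) <- sizes$chrom
  seqinfo(cen) <- si
  feat <- gr[!isCen]
  fk <- kind[!isCen]
  fid <- ids[!isCen]
  featOut <- GRanges(seqnames = as.character(GenomicRanges::seqnames(feat)),
                     ranges = IRanges::ranges(feat),
                     strand = GenomicRanges::strand(feat))
  GenomeInfoDb::seqlevels(featOut) <- sizes$chrom
  seqinfo(featOut) <- si
  featOut$kind <- fk
  featOut$id <- fid
  new("GenomeAnnotation", seqinfo = si, centromeres = cen, features = featOut)
}

#' Write a genome annotation to GFF3 + chromosome sizes
#'
#' Inverse of \code{\link{loadAnnotation}}: features and centromeres go to a
#' GFF3 file (kinds mapped back to GFF3 types), chromosome lengths to a
#' two-column TSV. A load of the written files reproduces the annotation.
#'
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @param gffPath output GFF3 path.
#' @param chromSizesPath output chrom-sizes TSV path.
#' @return invisibly, the two paths.
#' @export
writeAnnotation <- function(genome, gffPath, chromSizesPath) {
  stopifnot(is(genome, "GenomeAnnotation"))
  lens <- chromLengths(genome)
  utils::write.table(data.frame(chrom = names(lens), length = unname(lens)),
                     chromSizesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  feat <- genome@features
  typeMap <- c(gene = "gene", LTR = "long_terminal_repeat", ARS = "ARS",
               other = "region")
  grF <- granges(feat)
  grF$type <- unname(typeMap[feat$kind])
  grF$ID <- feat$id
  cen <- granges(genome@centromeres)
  if (length(cen)) {
    cen$type <- "centromere"
    cen$ID <- paste0("CEN_", as.character(GenomicRanges::seqnames(cen)))
  }
  allf <- c(grF, cen)
  allf <- GenomicRanges::sort(allf, ignore.strand = TRUE)
  rtracklayer::export(allf, gffPath, format = "gff3")
  invisible(c(gff = gffPath, sizes = chromSizesPath))
}

#' Read aligned reads from BED6
#'
#' One line per aligned single-end read; strand is taken from column 6.
#' Reads on chromosomes absent from the genome, or out of bounds, are a
#' hard error.
#'
#' @param path BED6 file of read alignments.
#' @param genome a \linkS4class{GenomeAnnotation}.
#' @return \code{GRanges} of reads with strand.
#' @export
readReadsBed <- function(path, genome) {
  stopifnot(is(genome, "GenomeAnnotation"))
  gr <- rtracklayer::import(path, format = "BED")
  lens <- chromLengths(genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (any(!chr %in% names(lens)))
    stop("reads on unknown chromosome: ",
         paste(setdiff(unique(chr), names(lens)), collapse = ", "))
  if (any(GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens[chr]))
    stop("reads outside chromosome bounds")
  if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
    stop("reads must be stranded (+/-)")
  out <- GRanges(chr, IRanges::ranges(gr), strand = GenomicRanges::strand(gr))
  GenomeInfoDb::seqlevels(out) <- names(lens)
  seqinfo(out) <- genome@seqinfo
  out
}

#' Write intervals to BED6
#'
#' Region sets are normalized (sorted, merged) before writing.
#'
#' @param gr a \code{GRanges}.
#' @param path output BED path.
#' @param merge merge overlapping intervals first (default \code{TRUE};
#'   set \code{FALSE} for stranded reads).
#' @return invisibly, \code{path}.
#' @export
writeBed <- function(gr, path, merge = TRUE) {
  if (merge) gr <- reduce(GenomicRanges::sort(gr, ignore.strand = TRUE),
                          ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
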