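# Sister-chromatid separation/segregation timing relative to spindle
# elongation, scored from per-cell live-imaging event tables.
#
# Input is a tidy table with one row per cell per frame:
#   cell_id, t_min, spindle_um, n_dots, compartment
# where compartment is one of "mother", "bud", "both", "na" and frames
# are spaced frameInterval minutes apart (0.5 min by default).

.checkFrames <- function(df) {
  need <- c("cell_id", "t_min", "spindle_um", "n_dots", "compartment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event table lacks columns: ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Read a per-frame cell event table (TSV)
#'
#' @param path TSV with columns \code{cell_id}, \code{t_min},
#'   \code{spindle_um}, \code{n_dots}, \code{compartment}.
#' @return a \code{data.frame} of frames, ordered by cell and time.
#' @export
readCellRecords <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  .checkFrames(df)
  df[order(df$cell_id, df$t_min), , drop = FALSE]
}

#' Detect spindle elongation in one cell
#'
#' Spindle elongation is the first frame at which the tubulin structure
#' exceeds the length threshold (strictly greater than; the default
#' 3.18 um corresponds to 10 pixels at 0.318 um/px).
#'
#' @param record data.frame of one cell's frames (columns \code{t_min},
#'   \code{spindle_um}), ordered by time.
#' @param threshold spindle length threshold in um (default 3.18).
#' @return the elongation time in minutes, or \code{NA} if the spindle
#'   never exceeds the threshold.
#' @export
detectSpindleElongation <- function(record, threshold = 3.18) {
  if (nrow(record) == 0L) stop("empty spindle series")
  hit <- which(record$spindle_um > threshold)
  if (length(hit) == 0L) return(NA_real_)
  record$t_min[hit[1]]
}

#' Classify separation/segregation timing of one cell
#'
#' Separation is the first frame at or after spindle elongation
#' (\code{t0}) with two visible chromatid dots; segregation the first
#' frame with one dot in the mother and one in the bud
#' (\code{compartment == "both"}). Cells are placed in one of four
#' latency categories: \code{"le5"} if segregation follows separation
#' within \code{latencyCut} minutes, \code{"gt5"} if later,
#' \code{"never_segregated"} if chromatids separate but never partition
#' within the \code{span}, and \code{"never_separated"} (the asterisk
#' category) if they never separate. Missegregation is scored as the
#' chromosome marker being absent from mother or daughter at the end of
#' the observation span.
#'
#' @param record data.frame of one cell's frames, ordered by time.
#' @param t0 spindle-elongation time from
#'   \code{\link{detectSpindleElongation}} (must not be \code{NA}).
#' @param latencyCut latency threshold in minutes (default 5).
#' @param span observation span in minutes (default 70).
#' @return one-row \code{data.frame}: \code{cell_id}, \code{t0},
#'   \code{separation_offset}, \code{segregation_offset},
#'   \code{category}, \code{missegregated}.
#' @export
classifyCell <- function(record, t0, latencyCut = 5, span = 70) {
  .checkFrames(record)
  if (is.na(t0)) stop("t0 is undefined; classify only spindle-elongated cells")
  record <- record[record$t_min <= span, , drop = FALSE]
  sepIdx <- which(record$n_dots == 2 & record$t_min >= t0)
  segIdx <- which(record$compartment == "both")
  sepT <- if (length(sepIdx)) record$t_min[sepIdx[1]] else NA_real_
  segT <- if (length(segIdx)) record$t_min[segIdx[1]] else NA_real_
  if (!is.na(segT) && (is.na(sepT) || segT < sepT))
    stop("inconsistent event table: segregation before separation (cell ",
         record$cell_id[1], ")")
  category <- if (is.na(sepT)) "never_separated"
    else if (is.na(segT)) "never_segregated"
    else if (segT - sepT <= latencyCut) "le5"
    else "gt5"
  lastComp <- record$compartment[nrow(record)]
  data.frame(cell_id = record$cell_id[1], t0 = t0,
             separation_offset = if (is.na(sepT)) NA_real_ else sepT - t0,
             segregation_offset = if (is.na(segT)) NA_real_ else segT - t0,
             category = category,
             missegregated = !identical(lastComp, "both"),
             stringsAsFactors = FALSE)
}

#' Classify every cell of a cohort
#'
#' Runs \code{\link{detectSpindleElongation}} and
#' \code{\link{classifyCell}} per cell. Cells whose spindle never
#' elongates are excluded (they are not part of the histogram
#' denominator, and missegregation is only scored among elongated cells);
#' their ids are returned in the \code{"noElongation"} attribute.
#'
#' @param frames data.frame of per-cell per-frame observations.
#' @param threshold spindle elongation threshold in um (default 3.18).
#' @param latencyCut latency threshold in minutes (default 5).
#' @param span observation span in minutes (default 70).
#' @return \code{data.frame} of per-cell outcomes.
#' @export
classifyCells <- function(frames, threshold = 3.18, latencyCut = 5,
                          span = 70) {
  .checkFrames(frames)
  ids <- unique(frames$cell_id)
  rows <- list()
  noEl <- character(0)
  for (id in ids) {
    rec <- frames[frames$cell_id == id, , drop = FALSE]
    rec <- rec[order(rec$t_min), , drop = FALSE]
    t0 <- detectSpindleElongation(rec, threshold)
    if (is.na(t0)) {
      noEl <- c(noEl, as.character(id))
      next
    }
    rows[[length(rows) + 1L]] <- classifyCell(rec, t0, latencyCut, span)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), t0 = numeric(0),
               separation_offset = numeric(0),
               segregation_offset = numeric(0),
               category = character(0), missegregated = logical(0))
  attr(out, "noElongation") <- noEl
  out
}

#' Aggregate timing outcomes into the 1-minute separation histogram
#'
#' Separation offsets (minutes after spindle elongation) are pooled
#' pairwise into 1-minute bins by \code{floor(offset)} -- the frames at
#' 0 and 0.5 min fall in bin 0, 1 and 1.5 min in bin 1, and so on --
#' split by latency category. Never-separated cells are tallied
#' separately, so that histogram counts plus the never-separated count
#' equal the number of spindle-elongated cells.
#'
#' @param outcomes per-cell outcome table from \code{\link{classifyCells}}.
#' @return a list with \code{histogram} (data.frame \code{bin},
#'   \code{category}, \code{count}), \code{neverSeparated} and
#'   \code{nCells}.
#' @export
aggregateHistogram <- function(outcomes) {
  sep <- outcomes[outcomes$category != "never_separated", , drop = FALSE]
  neverSep <- sum(outcomes$category == "never_separated")
  if (nrow(sep)) {
    bin <- floor(sep$separation_offset)
    tab <- stats::aggregate(list(count = rep(1L, nrow(sep))),
                            by = list(bin = bin, category = sep$category),
                            FUN = sum)
    tab <- tab[order(tab$bin, tab$category), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(bin = integer(0), category = character(0),
                      count = integer(0))
  }
  list(histogram = tab, neverSeparated = neverSep, nCells = nrow(outcomes))
}

#' Write per-cell outcomes and the timing histogram to TSV
#'
#' @param outcomes per-cell outcome table from \code{\link{classifyCells}}.
#' @param outcomesPath,histogramPath output TSV paths.
#' @return invisibly, the histogram list from
#'   \code{\link{aggregateHistogram}}.
#' @export
writeTimingTables <- function(outcomes, outcomesPath, histogramPath) {
  utils::write.table(outcomes, outcomesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  h <- aggregateHistogram(outcomes)
  utils::write.table(h$histogram, histogramPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(h)
}
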