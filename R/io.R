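# TSV / events.tsv / JSON round-tripping. ROI matrices are written as plain
# TSV with the ROI label in the first column and one column per TR; values
# are printed with full double precision (%.17g) so write -> read is exact.

#' Write an ROI time series as TSV
#'
#' @param ts a [roi_time_series].
#' @param path output file.
#' @export
write_roi_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_time_series"))
  df <- data.frame(roi_label = ts$roi_labels,
                   apply(ts$values, 2, function(col) sprintf("%.17g", col)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("roi_label", sprintf("tr%04d", seq_len(ncol(ts$values)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ROI time series from TSV
#'
#' @param path TSV written by [write_roi_tsv()] (first column `roi_label`).
#' @param tr_seconds repetition time to attach.
#' @return a [roi_time_series].
#' @export
read_roi_tsv <- function(path, tr_seconds = 1.8) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (colnames(df)[1] != "roi_label") stop("malformed header: first column must be 'roi_label'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- NULL
  if (anyNA(vals)) stop("ragged or non-numeric rows in ", path)
  roi_time_series(vals, df$roi_label, tr_seconds)
}

#' Write an event table as BIDS-style events.tsv
#'
#' Columns: onset, duration, trial_type (the phase), task, trial_index.
#'
#' @param events an event table.
#' @param path output file.
#' @export
write_events <- function(events, path) {
  df <- data.frame(onset = events$onset, duration = events$duration,
                   trial_type = events$phase, task = events$task,
                   trial_index = events$trial_index)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events.tsv
#'
#' @param path events.tsv with at least onset, duration, trial_type columns.
#' @return an `event_table` data.frame.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  for (col in c("onset", "duration", "trial_type")) {
    if (!col %in% colnames(df)) stop("events file missing required column '", col, "'")
  }
  ev <- data.frame(onset = as.numeric(df$onset), duration = as.numeric(df$duration),
                   phase = as.character(df$trial_type),
                   task = if ("task" %in% colnames(df)) df$task else NA_character_,
                   trial_index = if ("trial_index" %in% colnames(df))
                     as.integer(df$trial_index) else seq_len(nrow(df)),
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write a phase series with its JSON sidecar
#'
#' The TSV holds the concatenated matrix; the sidecar records phase, task,
#' session and segment boundaries so the series can be re-split exactly.
#'
#' @param series a `phase_series`.
#' @param path TSV path; the sidecar is written next to it as `<path>.json`.
#' @export
write_phase_series <- function(series, path) {
  ts <- roi_time_series(series$values, series$roi_labels,
                        series$tr_seconds %||% 1.8)
  write_roi_tsv(ts, path)
  side <- list(phase = series$phase, task = series$task,
               session = series$session, boundaries = series$boundaries,
               seg_lengths = series$seg_lengths)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
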