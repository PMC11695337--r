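#' Segment length schedule
#'
#' Event-locked segments are nominally 10 s long, i.e. 6-7 TRs at TR = 1.8 s,
#' and 60 of them concatenate to a 400-TR series (mean 20/3 TRs). A
#' deterministic repeating (7, 7, 6) pattern over trial index reproduces that
#' total exactly: 20 x (7 + 7 + 6) = 400.
#'
#' @param n_trials number of trials.
#' @param pattern repeating length pattern.
#' @return integer vector of `n_trials` segment lengths.
#' @export
segment_length_schedule <- function(n_trials, pattern = c(7L, 7L, 6L)) {
  if (n_trials <= 0) stop("n_trials must be positive")
  rep_len(as.integer(pattern), n_trials)
}

#' Extract event-locked segments for one phase
#'
#' Each segment starts at the TR containing the event onset (0-based TR index
#' `floor(onset / tr_seconds)`) and spans the schedule length for its trial.
#' Encoding segments deliberately overrun into the distractor period and
#' retrieval segments into the inter-trial interval; no truncation at event
#' offset is attempted.
#'
#' @param ts a [roi_time_series].
#' @param events an event table with columns onset, phase, trial_index.
#' @param phase `"encoding"` or `"retrieval"`.
#' @param schedule optional integer vector of per-trial segment lengths;
#'   defaults to [segment_length_schedule()] for the phase's event count.
#' @return object of class `segment_list`: list of segments, each with
#'   `trial_index`, `start_tr` (0-based), `length_tr`, `values`.
#' @export
extract_phase_segments <- function(ts, events, phase, schedule = NULL) {
  stopifnot(inherits(ts, "roi_time_series"))
  ev <- events[events$phase == phase, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events for phase '", phase, "'")
  ev <- ev[order(ev$onset), , drop = FALSE]
  if (is.null(schedule)) schedule <- segment_length_schedule(nrow(ev))
  n_trs <- ncol(ts$values)
  segs <- vector("list", nrow(ev))
  last_end <- -1L
  for (i in seq_len(nrow(ev))) {
    start <- as.integer(floor(ev$onset[i] / ts$tr_seconds))
    len <- schedule[ev$trial_index[i]]
    if (start + len > n_trs) {
      stop("segment for trial ", ev$trial_index[i], " exceeds series end (",
           start + len, " > ", n_trs, " TRs)")
    }
    if (start <= last_end) stop("segments overlap at trial ", ev$trial_index[i])
    last_end <- start + len - 1L
    segs[[i]] <- list(trial_index = ev$trial_index[i], start_tr = start,
                      length_tr = len,
                      values = ts$values[, start + seq_len(len), drop = FALSE])
  }
  structure(segs, class = "segment_list", roi_labels = ts$roi_labels,
            tr_seconds = ts$tr_seconds)
}

#' Concatenate segments into a per-phase series
#'
#' Columns are the segments' columns in order of appearance; cumulative
#' segment end offsets are recorded as boundaries so the concatenation can be
#' re-split exactly.
#'
#' @param segments a `segment_list`.
#' @param phase,task,session optional provenance labels stored on the result.
#' @return object of class `phase_series` with `values`, `phase`, `task`,
#'   `session`, `boundaries` (cumulative end offsets) and `seg_lengths`.
#' @export
concatenate_segments <- function(segments, phase = NA_character_,
                                 task = NA_character_, session = NA_integer_) {
  if (length(segments) == 0) stop("empty segment list")
  n_rois <- nrow(segments[[1]]$values)
  for (s in segments) {
    if (nrow(s$values) != n_rois) stop("inconsistent ROI counts across segments")
  }
  lens <- vapply(segments, function(s) s$length_tr, integer(1))
  values <- do.call(cbind, lapply(segments, function(s) s$values))
  structure(list(values = values, phase = phase, task = task, session = session,
                 boundaries = cumsum(lens), seg_lengths = lens,
                 roi_labels = attr(segments, "roi_labels"),
                 tr_seconds = attr(segments, "tr_seconds")),
            class = "phase_series")
}

#' Re-split a phase series at its recorded boundaries
#'
#' Inverse of [concatenate_segments()]; used to verify the round-trip
#' invariant and to enumerate segments for temporal (t = 6) sampling.
#'
#' @param series a `phase_series`.
#' @return list of value matrices, one per segment.
#' @export
split_phase_series <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  starts <- c(0L, utils::head(series$boundaries, -1L))
  Map(function(s, l) series$values[, s + seq_len(l), drop = FALSE],
      starts, series$seg_lengths)
}

#' Build a shuffled rest series
#'
#' Emulates rest preprocessing: a contiguous 400-TR window is chosen
#' uniformly at random from the rest session, cut into consecutive
#' non-overlapping segments following the default length schedule, the
#' segment order is permuted uniformly at random, and the segments are
#' concatenated.
#'
#' @param ts a rest [roi_time_series] with at least 400 TRs.
#' @param seed integer seed controlling window choice and permutation.
#' @param total_trs window length (default 400).
#' @param session optional provenance label.
#' @return a `phase_series` with phase `"rest"`, task `"REST"`, 400 TRs.
#' @export
build_rest_series <- function(ts, seed, total_trs = 400L, session = NA_integer_) {
  stopifnot(inherits(ts, "roi_time_series"))
  n_trs <- ncol(ts$values)
  if (n_trs < total_trs) {
    stop("rest series has ", n_trs, " TRs; at least ", total_trs, " required")
  }
  # schedule segments filling total_trs exactly: repeating (7,7,6)
  lens <- integer(0)
  pat <- c(7L, 7L, 6L)
  while (sum(lens) < total_trs) lens <- c(lens, pat[length(lens) %% 3L + 1L])
  if (sum(lens) != total_trs) stop("total_trs not representable by the (7,7,6) schedule")
  set.seed(seed)
  start0 <- sample.int(n_trs - total_trs + 1L, 1L) - 1L  # 0-based window start
  window <- ts$values[, start0 + seq_len(total_trs), drop = FALSE]
  starts <- c(0L, cumsum(utils::head(lens, -1L)))
  segs <- Map(function(s, l) window[, s + seq_len(l), drop = FALSE], starts, lens)
  perm <- sample.int(length(segs))
  segs <- segs[perm]
  lens <- lens[perm]
  structure(list(values = do.call(cbind, segs), phase = "rest", task = "REST",
                 session = session, boundaries = cumsum(lens), seg_lengths = lens,
                 roi_labels = ts$roi_labels, tr_seconds = ts$tr_seconds),
            class = "phase_series")
}

#' Segment a full study into phase series
#'
#' Applies [extract_phase_segments()] and [concatenate_segments()] to every
#' task session for both phases, and [build_rest_series()] to every rest
#' session (with a seed derived from `base_seed` and the session index).
#'
#' @param study result of [generate_study()] (or an equivalent list of
#'   sessions with ts/events entries).
#' @param base_seed seed base for rest-window randomization.
#' @return list of `phase_series` objects.
#' @export
segment_study <- function(study, base_seed = 1L) {
  out <- list()
  rest_i <- 0L
  for (sess in study$sessions) {
    if (identical(sess$task, "REST")) {
      rest_i <- rest_i + 1L
      out[[length(out) + 1L]] <-
        build_rest_series(sess$ts, seed = base_seed + rest_i, session = sess$session)
    } else {
      for (phase in c("encoding", "retrieval")) {
        segs <- extract_phase_segments(sess$ts, sess$events, phase)
        out[[length(out) + 1L]] <-
          concatenate_segments(segs, phase = phase, task = sess$task,
                               session = sess$session)
      }
    }
  }
  out
}
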