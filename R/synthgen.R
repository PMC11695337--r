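#' Default informative-ROI layout
#'
#' Builds the default map from (phase, task) to the set of ROI indices that
#' carry task-discriminative signal. Eight ROIs per task with four shared
#' between the two visuospatial tasks (GLO/LOC) and four between the two
#' verbal tasks (SEM/PHO), so that the 2-class groupings remain learnable
#' while the 4-class problems stay separable. Encoding and retrieval use
#' disjoint blocks of ROIs.
#'
#' @param n_rois total number of ROIs; must be at least 48 for the default
#'   layout (use a custom map for smaller synthetic atlases).
#' @return nested list `informative_rois[[phase]][[task]]` of 1-based ROI
#'   index vectors.
#' @export
default_informative_rois <- function(n_rois = 116) {
  if (n_rois < 48) {
    stop("default informative layout needs n_rois >= 48; supply informative_rois explicitly")
  }
  block <- function(offset) {
    list(
      GLO = offset + c(1:4, 5:8),    # 1:4 shared visuospatial
      LOC = offset + c(1:4, 9:12),
      SEM = offset + c(13:16, 17:20), # 13:16 shared verbal
      PHO = offset + c(13:16, 21:24)
    )
  }
  list(encoding = block(0L), retrieval = block(24L))
}

#' Synthetic study generator configuration
#'
#' Describes a synthetic ROI-BOLD study emulating an event-related
#' working-memory experiment: four task conditions plus rest, 60 trials per
#' session each with an encoding and a retrieval event, TR = 1.8 s, and 116
#' atlas ROIs. Noise is stationary unit-variance AR(1) per ROI; informative
#' ROIs receive an additive activation of `effect_size` scaled by a per-TR
#' `temporal_profile` during each event's segment window.
#'
#' @param n_rois number of ROIs (rows of every generated matrix).
#' @param tasks character vector of task labels.
#' @param include_rest also generate resting-state sessions.
#' @param n_trials trials (stimulus sets) per task session.
#' @param tr_seconds repetition time in seconds.
#' @param n_sessions sessions per task.
#' @param effect_size standardized mean shift per informative ROI at profile
#'   weight 1 (noise has unit variance, so this is Cohen's d at segment peak).
#' @param informative_rois nested list `[[phase]][[task]]` of ROI indices, or
#'   NULL for [default_informative_rois()].
#' @param duplicate_pairs list of `c(src, dst, noise_sd)` triples; after
#'   signal injection, row `dst` is replaced by row `src` plus independent
#'   Gaussian noise, creating highly correlated ROI pairs.
#' @param ar_coefficient AR(1) coefficient of the noise, in \[0, 1).
#' @param temporal_profile weight vector applied across the TRs of a segment
#'   (recycled at its last value for longer segments). The default 6-point
#'   linear ramp gives temporal models an exploitable within-segment signature.
#' @param rest_trs length of a rest session in TRs (must allow a 400-TR window).
#' @param seed base seed from which per-session seeds are derived.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_rois = 116L,
                             tasks = c("GLO", "LOC", "SEM", "PHO"),
                             include_rest = TRUE,
                             n_trials = 60L,
                             tr_seconds = 1.8,
                             n_sessions = 1L,
                             effect_size = 0.8,
                             informative_rois = NULL,
                             duplicate_pairs = NULL,
                             ar_coefficient = 0.4,
                             temporal_profile = seq(1 / 6, 1, length.out = 6),
                             rest_trs = 450L,
                             seed = 1L) {
  if (n_trials <= 0) stop("n_trials must be positive")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (ar_coefficient < 0 || ar_coefficient >= 1) stop("ar_coefficient must be in [0, 1)")
  if (is.null(informative_rois)) {
    informative_rois <- if (n_rois >= 48) default_informative_rois(n_rois) else
      list(encoding = list(), retrieval = list())
  }
  for (phase in names(informative_rois)) {
    for (task in names(informative_rois[[phase]])) {
      idx <- informative_rois[[phase]][[task]]
      if (any(idx < 1L | idx > n_rois)) {
        stop("informative ROI index out of range for ", phase, "/", task)
      }
    }
  }
  if (!is.null(duplicate_pairs)) {
    for (p in duplicate_pairs) {
      stopifnot(length(p) == 3L)
      if (p[1] == p[2]) stop("duplicate pair source and target must differ")
      if (any(p[1:2] < 1 | p[1:2] > n_rois)) stop("duplicate pair index out of range")
    }
  }
  structure(list(
    n_rois = as.integer(n_rois), tasks = tasks, include_rest = include_rest,
    n_trials = as.integer(n_trials), tr_seconds = tr_seconds,
    n_sessions = as.integer(n_sessions), effect_size = effect_size,
    informative_rois = informative_rois, duplicate_pairs = duplicate_pairs,
    ar_coefficient = ar_coefficient, temporal_profile = temporal_profile,
    rest_trs = as.integer(rest_trs), seed = as.integer(seed)
  ), class = "generator_config")
}

#' ROI time-series container
#'
#' @param values numeric matrix, ROIs in rows, TRs in columns.
#' @param roi_labels character labels, one per row.
#' @param tr_seconds repetition time in seconds.
#' @return object of class `roi_time_series`.
#' @export
roi_time_series <- function(values, roi_labels = NULL, tr_seconds = 1.8) {
  values <- as.matrix(values)
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(nrow(values)))
  if (length(roi_labels) != nrow(values)) stop("roi_labels length must equal row count")
  if (anyNA(values)) stop("ROI time series must not contain missing values")
  rownames(values) <- roi_labels
  structure(list(values = values, roi_labels = roi_labels, tr_seconds = tr_seconds),
            class = "roi_time_series")
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("<roi_time_series> %d ROIs x %d TRs (TR = %.2f s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

# Internal: trial layout in TRs. A 12-TR (21.6 s at TR 1.8) trial period keeps
# consecutive same-phase segments (<= 7 TRs) non-overlapping; retrieval onsets
# sit 5 TRs (9 s) after encoding onsets, and a 5-TR tail pads the session so
# the last retrieval segment fits. 60 trials -> 725 TRs per session.
.trial_period_trs <- 12L
.retrieval_offset_trs <- 5L
.session_tail_trs <- 5L

#' Build the event table for one task session
#'
#' @param config a [generator_config()].
#' @param task task label.
#' @return data.frame with columns onset, duration, phase, task, trial_index
#'   (class `event_table`). REST sessions get zero rows.
#' @export
make_event_table <- function(config, task) {
  if (identical(task, "REST")) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     phase = character(0), task = character(0),
                     trial_index = integer(0), stringsAsFactors = FALSE)
    class(ev) <- c("event_table", "data.frame")
    return(ev)
  }
  tr <- config$tr_seconds
  i <- seq_len(config$n_trials)
  enc <- data.frame(onset = (i - 1) * .trial_period_trs * tr, duration = 1.5,
                    phase = "encoding", task = task, trial_index = i,
                    stringsAsFactors = FALSE)
  ret <- data.frame(onset = (i - 1) * .trial_period_trs * tr + .retrieval_offset_trs * tr,
                    duration = 2.0, phase = "retrieval", task = task,
                    trial_index = i, stringsAsFactors = FALSE)
  ev <- rbind(enc, ret)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

# Internal: one stationary unit-variance AR(1) series of length n.
.ar1_series <- function(n, phi) {
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  x0 <- stats::rnorm(1)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

#' Generate one synthetic session
#'
#' Produces an ROI x TR matrix of stationary unit-variance AR(1) Gaussian
#' noise. For a task session, each event whose (task, phase) has an
#' informative ROI set receives an additive shift of
#' `effect_size * temporal_profile` on those ROIs over the event's segment
#' window (the same onset-locked window the segmentation step extracts).
#' Duplicate pairs are then injected. REST sessions are pure noise.
#'
#' @param config a [generator_config()].
#' @param task task label in `config$tasks` or `"REST"`.
#' @param seed integer seed; identical config+seed gives bit-identical output.
#' @return list with elements `ts` ([roi_time_series]) and `events`
#'   (event table; empty for REST).
#' @export
generate_session <- function(config, task, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!(task %in% config$tasks || identical(task, "REST"))) {
    stop("unknown task label: ", task)
  }
  events <- make_event_table(config, task)
  n_trs <- if (identical(task, "REST")) config$rest_trs else
    config$n_trials * .trial_period_trs + .session_tail_trs
  set.seed(seed)
  vals <- matrix(0, config$n_rois, n_trs)
  for (r in seq_len(config$n_rois)) {
    vals[r, ] <- .ar1_series(n_trs, config$ar_coefficient)
  }
  if (nrow(events) > 0 && config$effect_size > 0) {
    sched <- segment_length_schedule(config$n_trials)
    for (phase in c("encoding", "retrieval")) {
      rois <- config$informative_rois[[phase]][[task]]
      if (is.null(rois) || length(rois) == 0) next
      ev <- events[events$phase == phase, , drop = FALSE]
      for (j in seq_len(nrow(ev))) {
        len <- sched[ev$trial_index[j]]
        start <- floor(ev$onset[j] / config$tr_seconds)  # 0-based TR
        cols <- start + seq_len(len)                      # 1-based columns
        w <- config$temporal_profile[pmin(seq_len(len), length(config$temporal_profile))]
        vals[rois, cols] <- vals[rois, cols] +
          matrix(config$effect_size * w, length(rois), len, byrow = TRUE)
      }
    }
  }
  ts <- roi_time_series(vals, tr_seconds = config$tr_seconds)
  if (!is.null(config$duplicate_pairs)) {
    ts <- inject_duplicates(ts, config$duplicate_pairs)
  }
  list(ts = ts, events = events)
}

#' Duplicate ROI rows with additive noise
#'
#' Replaces the target row of each pair with the source row plus independent
#' Gaussian noise, creating the highly correlated / duplicated feature regime
#' that correlation-aware importance methods must handle. For a unit-variance
#' source and noise sd `s`, the population correlation is `1 / sqrt(1 + s^2)`.
#'
#' @param ts a [roi_time_series].
#' @param pairs list of numeric triples `c(src, dst, noise_sd)` (1-based
#'   indices).
#' @return a new [roi_time_series]; rows other than the targets are untouched.
#' @export
inject_duplicates <- function(ts, pairs) {
  stopifnot(inherits(ts, "roi_time_series"))
  vals <- ts$values
  for (p in pairs) {
    src <- as.integer(p[1]); dst <- as.integer(p[2]); sd <- p[3]
    if (src == dst) stop("duplicate pair source and target must differ")
    if (src < 1 || src > nrow(vals) || dst < 1 || dst > nrow(vals)) {
      stop("duplicate pair index out of range")
    }
    noise <- if (sd > 0) stats::rnorm(ncol(vals), sd = sd) else 0
    vals[dst, ] <- vals[src, ] + noise
  }
  roi_time_series(vals, ts$roi_labels, ts$tr_seconds)
}

#' Generate a full synthetic study
#'
#' One session per task per `n_sessions` (plus rest sessions when
#' `include_rest`), with per-session seeds derived deterministically from
#' `config$seed`, and a ground-truth record of the planted structure for
#' recovery tests.
#'
#' @param config a [generator_config()].
#' @return list with `sessions` (each a list of task, session, ts, events)
#'   and `ground_truth` (informative sets, duplicate pairs, effect size).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tasks <- config$tasks
  if (config$include_rest) tasks <- c(tasks, "REST")
  n_series <- length(tasks) * config$n_sessions
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_series)
  sessions <- vector("list", n_series)
  i <- 0L
  for (task in tasks) {
    for (s in seq_len(config$n_sessions)) {
      i <- i + 1L
      out <- generate_session(config, task, seed = seeds[i])
      sessions[[i]] <- list(task = task, session = s, ts = out$ts,
                            events = out$events, seed = seeds[i])
    }
  }
  ground_truth <- list(informative_rois = config$informative_rois,
                       duplicate_pairs = config$duplicate_pairs,
                       effect_size = config$effect_size)
  list(sessions = sessions, ground_truth = ground_truth)
}
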