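#' Classification problem specifications
#'
#' The eight decoding problems: per phase (encoding/retrieval), a 2-class
#' grouping of visuospatial (GLO, LOC) vs verbal (SEM, PHO) tasks, the same
#' plus rest (3 classes), the four tasks separately (4 classes), and the four
#' tasks plus rest (5 classes).
#'
#' @param name one of ENC2, ENC3, ENC4, ENC5, RET2, RET3, RET4, RET5.
#' @return object of class `problem_spec` with `name`, `phase`, `class_map`
#'   (named integer vector, task label to 0-based class index), `class_names`,
#'   `includes_rest`, `n_classes`.
#' @export
problem_spec <- function(name) {
  valid <- c("ENC2", "ENC3", "ENC4", "ENC5", "RET2", "RET3", "RET4", "RET5")
  if (!name %in% valid) {
    stop("unknown problem name '", name, "'; must be one of ",
         paste(valid, collapse = ", "))
  }
  phase <- if (startsWith(name, "ENC")) "encoding" else "retrieval"
  k <- as.integer(substring(name, 4))
  cm <- switch(as.character(k),
    "2" = c(GLO = 0L, LOC = 0L, SEM = 1L, PHO = 1L),
    "3" = c(GLO = 0L, LOC = 0L, SEM = 1L, PHO = 1L, REST = 2L),
    "4" = c(GLO = 0L, LOC = 1L, SEM = 2L, PHO = 3L),
    "5" = c(GLO = 0L, LOC = 1L, SEM = 2L, PHO = 3L, REST = 4L)
  )
  class_names <- switch(as.character(k),
    "2" = c("GLO+LOC", "SEM+PHO"),
    "3" = c("GLO+LOC", "SEM+PHO", "REST"),
    "4" = c("GLO", "LOC", "SEM", "PHO"),
    "5" = c("GLO", "LOC", "SEM", "PHO", "REST")
  )
  structure(list(name = name, phase = phase, class_map = cm,
                 class_names = class_names,
                 includes_rest = "REST" %in% names(cm), n_classes = k),
            class = "problem_spec")
}

#' Build samples from one phase series
#'
#' With `t = 1` every TR column becomes one `n_rois x 1` sample (400 per
#' 400-TR series). With `t = 6` each segment yields exactly one
#' `n_rois x 6` sample from its first six TRs (7-TR segments drop their last
#' TR); windows are one-per-segment and non-overlapping.
#'
#' @param series a `phase_series`.
#' @param t samples' temporal extent, 1 or 6.
#' @return 3-d array of shape `n_samples x n_rois x t`.
#' @export
make_samples <- function(series, t) {
  stopifnot(inherits(series, "phase_series"))
  if (!t %in% c(1L, 6L)) stop("t must be 1 or 6")
  v <- series$values
  if (t == 1L) {
    x <- array(0, c(ncol(v), nrow(v), 1L))
    x[, , 1L] <- t(v)
    return(x)
  }
  if (any(series$seg_lengths < 6L)) stop("segment shorter than 6 TRs with t = 6")
  segs <- split_phase_series(series)
  x <- array(0, c(length(segs), nrow(v), 6L))
  for (i in seq_along(segs)) x[i, , ] <- segs[[i]][, 1:6, drop = FALSE]
  x
}

#' Assemble a labeled dataset for one classification problem
#'
#' Selects the phase series matching the problem's phase (rest series match
#' every phase when the problem includes rest), converts each to samples via
#' [make_samples()], and labels them by the problem's class map.
#'
#' @param phase_series_list list of `phase_series` (e.g. [segment_study()]).
#' @param spec a [problem_spec()] or problem name string.
#' @param t samples' temporal extent, 1 or 6.
#' @return object of class `rd_dataset`: list with `x`
#'   (`n x n_rois x t` array), `y` (0-based integer labels), `class_names`,
#'   `t`, and `provenance` (task/session per sample).
#' @export
assemble_problem <- function(phase_series_list, spec, t = 1L) {
  if (is.character(spec)) spec <- problem_spec(spec)
  stopifnot(inherits(spec, "problem_spec"))
  tasks_needed <- names(spec$class_map)
  keep <- Filter(function(ps) {
    ps$task %in% tasks_needed &&
      (ps$phase == spec$phase || (identical(ps$task, "REST") && ps$phase == "rest"))
  }, phase_series_list)
  present <- unique(vapply(keep, function(ps) ps$task, character(1)))
  missing <- setdiff(tasks_needed, present)
  if (length(missing) > 0) {
    stop("problem ", spec$name, " needs series for: ", paste(missing, collapse = ", "))
  }
  xs <- list(); ys <- list(); prov <- list()
  for (ps in keep) {
    x <- make_samples(ps, t)
    xs[[length(xs) + 1L]] <- x
    ys[[length(ys) + 1L]] <- rep(spec$class_map[[ps$task]], dim(x)[1])
    prov[[length(prov) + 1L]] <- data.frame(task = ps$task, session = ps$session,
                                            stringsAsFactors = FALSE)[rep(1, dim(x)[1]), ]
  }
  n <- sum(vapply(xs, function(a) dim(a)[1], integer(1)))
  x <- array(0, c(n, dim(xs[[1]])[2], t))
  off <- 0L
  for (a in xs) {
    x[off + seq_len(dim(a)[1]), , ] <- a
    off <- off + dim(a)[1]
  }
  prov <- do.call(rbind, prov)
  rownames(prov) <- NULL
  structure(list(x = x, y = as.integer(unlist(ys)), class_names = spec$class_names,
                 t = as.integer(t), problem = spec$name, provenance = prov),
            class = "rd_dataset")
}

#' @export
print.rd_dataset <- function(x, ...) {
  cat(sprintf("<rd_dataset> %s: %d samples of %d ROIs x %d TR(s), %d classes\n",
              ifelse(is.null(x$problem), "?", x$problem), dim(x$x)[1],
              dim(x$x)[2], dim(x$x)[3], length(x$class_names)))
  print(table(class = x$class_names[x$y + 1L]))
  invisible(x)
}

# Internal: subset an rd_dataset by sample indices.
dataset_subset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , , drop = FALSE], y = ds$y[idx],
                 class_names = ds$class_names, t = ds$t, problem = ds$problem,
                 provenance = ds$provenance[idx, , drop = FALSE]),
            class = "rd_dataset")
}

#' Random train/test split
#'
#' Sample-level random partition, stratified by class by default so class
#' proportions are preserved within one sample per class. A grouped
#' (session-wise) split is available via `by_session = TRUE` for evaluation
#' that respects temporal autocorrelation within sessions.
#'
#' @param ds an `rd_dataset`.
#' @param ratio training fraction (default 0.9, i.e. a 90:10 split).
#' @param seed integer seed; identical seed gives identical partitions.
#' @param stratified preserve class proportions (default TRUE).
#' @param by_session assign whole sessions to one side (default FALSE).
#' @return object of class `rd_split` with `train`, `test`, `ratio`, `seed`.
#' @export
split_train_test <- function(ds, ratio = 0.9, seed = 1L, stratified = TRUE,
                             by_session = FALSE) {
  stopifnot(inherits(ds, "rd_dataset"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n <- length(ds$y)
  set.seed(seed)
  if (by_session) {
    key <- interaction(ds$provenance$task, ds$provenance$session, drop = TRUE)
    groups <- levels(key)
    n_test_g <- max(1L, round((1 - ratio) * length(groups)))
    test_groups <- sample(groups, n_test_g)
    test_idx <- which(key %in% test_groups)
  } else if (stratified) {
    test_idx <- integer(0)
    for (cl in sort(unique(ds$y))) {
      idx <- which(ds$y == cl)
      if (length(idx) < 2L) stop("class ", cl, " has fewer than 2 samples")
      n_test <- max(1L, round((1 - ratio) * length(idx)))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  } else {
    test_idx <- sample.int(n, max(1L, round((1 - ratio) * n)))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  structure(list(train = dataset_subset(ds, train_idx),
                 test = dataset_subset(ds, sort(test_idx)),
                 train_idx = train_idx, test_idx = sort(test_idx),
                 ratio = ratio, seed = seed), class = "rd_split")
}

# Internal: flatten samples to an n x (rois*t) matrix for tabular models.
flatten_samples <- function(x) {
  d <- dim(x)
  matrix(x, d[1], d[2] * d[3])
}
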