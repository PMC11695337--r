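#' Split counts of a fitted tree ensemble
#'
#' Counts how many times each feature is used to split a node, summed over
#' all trees — the default feature-importance notion for gradient-boosted
#' trees. Features never used score 0.
#'
#' @param model a gradient-boosting `rd_classifier` (or the list returned by
#'   the internal gbm fitter).
#' @return named integer vector over all training features, in training
#'   column order.
#' @export
split_counts <- function(model) {
  fit <- if (inherits(model, "rd_classifier")) {
    if (!model$spec$name %in% c("gradient_boosting", "gradient_boosting_tuned")) {
      stop("split_counts requires a tree-based gradient-boosting classifier")
    }
    model$fit
  } else if (is.list(model) && !is.null(model$booster)) {
    model
  } else {
    stop("split_counts requires a fitted tree-ensemble model")
  }
  tree_df <- xgboost::xgb.model.dt.tree(model = fit$booster)
  feats <- fit$feature_names
  counts <- stats::setNames(integer(length(feats)), feats)
  used <- tree_df$Feature[tree_df$Feature != "Leaf"]
  tab <- table(used)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# z-score a vector; all-equal input (zero sd) maps to all zeros
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Default pruning classifier factory: untuned gradient boosting
#'
#' @param nrounds boosting rounds per refit.
#' @return function(x, y, n_classes, seed) returning a fitted model usable by
#'   [split_counts()] and [predict_labels()].
#' @export
gbm_factory <- function(nrounds = 100L) {
  function(x, y, n_classes, seed) {
    fit_classifier(classifier_spec("gradient_boosting",
                                   list(nrounds = nrounds)),
                   x, y, n_classes = n_classes, seed = seed)
  }
}

#' Correlation-aware ROI importance by iterative pruning
#'
#' Split-count importance cannot see feature correlations: of two equally
#' informative, highly correlated ROIs, one can absorb all splits and the
#' other score near zero. This procedure corrects for that by iterating:
#' fit the classifier on the remaining ROIs, compute split counts, z-score
#' them across the remaining ROIs (correcting for the shrinking feature
#' count), append each ROI's z-score to its buffer, then remove the
#' highest-scoring ROI (ties broken by lowest index). The loop runs until a
#' single ROI survives; the survivor is appended to the removal order with
#' its last buffered score. The final score of an ROI is the median (or
#' mean) of its buffer over all steps in which it was present.
#'
#' @param train,test `rd_dataset`s (t = 1); the test set only feeds the
#'   informational per-step F1 trace.
#' @param factory classifier constructor `function(x, y, n_classes, seed)`;
#'   default untuned gradient boosting ([gbm_factory()]).
#' @param seed integer seed (per-step fits derive from it).
#' @param aggregate `"median"` (default) or `"mean"` buffer aggregation.
#' @return object of class `pruning_trace`: `removal_order` (1-based ROI
#'   indices, a permutation), `raw_scores` and `z_scores` (per-step named
#'   vectors over surviving ROIs), `buffers` (per-ROI z-score histories),
#'   `final_scores`, `step_f1`.
#' @export
prune_importance <- function(train, test, factory = gbm_factory(), seed = 1L,
                             aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(train, "rd_dataset"))
  x_all <- flatten_samples(train$x)
  xt_all <- flatten_samples(test$x)
  n_rois <- ncol(x_all)
  if (n_rois < 2L) stop("need at least 2 ROIs")
  colnames(x_all) <- colnames(xt_all) <- sprintf("f%04d", seq_len(n_rois))
  n_classes <- length(train$class_names)
  remaining <- seq_len(n_rois)
  removal_order <- integer(0)
  raw_scores <- list()
  z_scores <- list()
  buffers <- rep(list(numeric(0)), n_rois)
  step_f1 <- numeric(0)
  step <- 0L
  while (length(remaining) > 1L) {
    step <- step + 1L
    model <- factory(x_all[, remaining, drop = FALSE], train$y, n_classes,
                     seed + step)
    s <- split_counts(model)
    if (any(!is.finite(s))) stop("non-finite importance scores at step ", step)
    names(s) <- as.character(remaining)
    z <- zscore0(as.numeric(s))
    names(z) <- names(s)
    raw_scores[[step]] <- s
    z_scores[[step]] <- z
    for (j in seq_along(remaining)) {
      r <- remaining[j]
      buffers[[r]] <- c(buffers[[r]], z[j])
    }
    step_f1 <- c(step_f1,
                 weighted_f1(test$y,
                             predict_labels(model, xt_all[, remaining, drop = FALSE]),
                             classes = 0:(n_classes - 1L))$weighted_f1)
    r_star <- remaining[which.max(z)]  # which.max: first max, lowest index
    removal_order <- c(removal_order, r_star)
    remaining <- setdiff(remaining, r_star)
  }
  # lone survivor: its last buffered value stands; no degenerate 1-feature fit
  survivor <- remaining
  buffers[[survivor]] <- c(buffers[[survivor]],
                           utils::tail(buffers[[survivor]], 1L) %||% 0)
  removal_order <- c(removal_order, survivor)
  agg_fun <- if (aggregate == "median") stats::median else mean
  final_scores <- vapply(buffers, function(b) if (length(b)) agg_fun(b) else NA_real_,
                         numeric(1))
  structure(list(removal_order = removal_order, raw_scores = raw_scores,
                 z_scores = z_scores, buffers = buffers,
                 final_scores = final_scores, step_f1 = step_f1,
                 n_rois = n_rois, aggregate = aggregate),
            class = "pruning_trace")
}

#' @export
print.pruning_trace <- function(x, ...) {
  cat(sprintf("<pruning_trace> %d ROIs, %d pruning steps (%s aggregation)\n",
              x$n_rois, length(x$z_scores), x$aggregate))
  top <- order(x$final_scores, decreasing = TRUE)[seq_len(min(5, x$n_rois))]
  cat("top ROIs:", paste(sprintf("%d (%.2f)", top, x$final_scores[top]),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Importance-change matrix across pruning steps
#'
#' Row n holds, for every ROI still present after removal n, the change in
#' z-scored importance caused by that removal:
#' `delta_n(r) = s_without_rstar(r) - s_with_rstar(r)`. Removing one of two
#' correlated informative ROIs shows up as a positive delta on its twin.
#' Cells of already-removed ROIs are NA; the per-step removal mask is
#' attached as attribute `removed`.
#'
#' @param trace a `pruning_trace`.
#' @return numeric matrix (steps-1) x n_rois with NA at masked cells.
#' @export
delta_matrix <- function(trace) {
  stopifnot(inherits(trace, "pruning_trace"))
  n_steps <- length(trace$z_scores)
  if (n_steps < 2L) stop("trace has fewer than 2 steps")
  D <- matrix(NA_real_, n_steps - 1L, trace$n_rois)
  removed <- matrix(FALSE, n_steps - 1L, trace$n_rois)
  for (n in seq_len(n_steps - 1L)) {
    after <- trace$z_scores[[n + 1L]]
    before <- trace$z_scores[[n]]
    keep <- names(after)
    D[n, as.integer(keep)] <- after[keep] - before[keep]
    removed[n, trace$removal_order[seq_len(n)]] <- TRUE
  }
  attr(D, "removed") <- removed
  D
}
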