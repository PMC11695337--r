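#' Hyperparameter search space for gradient boosting
#'
#' Bounds for the six tuned gradient-boosting hyperparameters: L1/L2
#' regularization in \[1e-8, 10\] (sampled log-uniformly), leaf count in
#' \[2, 128\], feature and bagging fractions in \[0.1, 1.0\], bagging
#' frequency in \[1, 7\].
#'
#' @param n_trials number of random configurations to draw (default 100).
#' @return object of class `search_space`.
#' @export
search_space <- function(n_trials = 100L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(
    lambda_l1 = c(1e-8, 10), lambda_l2 = c(1e-8, 10),
    num_leaves = c(2L, 128L), feature_fraction = c(0.1, 1.0),
    bagging_fraction = c(0.1, 1.0), bagging_freq = c(1L, 7L),
    n_trials = as.integer(n_trials)
  ), class = "search_space")
}

# Internal: draw one configuration uniformly within the space
# (log-uniform for the regularization terms).
sample_gbm_config <- function(space) {
  lu <- function(b) exp(stats::runif(1, log(b[1]), log(b[2])))
  list(
    lambda_l1 = lu(space$lambda_l1),
    lambda_l2 = lu(space$lambda_l2),
    num_leaves = sample(space$num_leaves[1]:space$num_leaves[2], 1L),
    feature_fraction = stats::runif(1, space$feature_fraction[1], space$feature_fraction[2]),
    bagging_fraction = stats::runif(1, space$bagging_fraction[1], space$bagging_fraction[2]),
    bagging_freq = sample(space$bagging_freq[1]:space$bagging_freq[2], 1L)
  )
}

#' Random-search tuning of the gradient-boosting classifier
#'
#' Carves a stratified 80:20 fit/validation sub-split out of the training
#' partition (the held-out test set is never touched), evaluates `n_trials`
#' uniformly sampled configurations plus the default configuration, and
#' returns the one with the highest validation weighted F1. The seeded
#' uniform random search replaces a Bayesian (TPE) optimizer while keeping
#' the same search-space semantics; the default configuration is always a
#' candidate, so the winner's validation score is never below the default's.
#'
#' @param split an `rd_split` (t = 1).
#' @param space a [search_space()].
#' @param seed integer seed; same seed reproduces the trial sequence.
#' @param nrounds boosting rounds per trial fit.
#' @return list with `best` (hyperparameter list), `validation_f1`, and
#'   `trials` (data.frame of every configuration and its score).
#' @export
tune_gradient_boosting <- function(split, space = search_space(), seed = 1L,
                                   nrounds = 100L) {
  stopifnot(inherits(split, "rd_split"))
  inner <- split_train_test(split$train, ratio = 0.8, seed = seed,
                            stratified = TRUE)
  xf <- flatten_samples(inner$train$x); yf <- inner$train$y
  xv <- flatten_samples(inner$test$x); yv <- inner$test$y
  n_classes <- length(split$train$class_names)
  default_cfg <- list(lambda_l1 = 0, lambda_l2 = 1, num_leaves = 31L,
                      feature_fraction = 1, bagging_fraction = 1, bagging_freq = 0L)
  set.seed(seed)
  configs <- c(list(default_cfg),
               lapply(seq_len(space$n_trials), function(i) sample_gbm_config(space)))
  scores <- numeric(length(configs))
  for (i in seq_along(configs)) {
    hp <- c(configs[[i]], list(nrounds = nrounds))
    fit <- fit_gbm(xf, yf, n_classes, hp, seed = seed + i)
    scores[i] <- weighted_f1(yv, predict_gbm(fit, xv))$weighted_f1
  }
  best_i <- which.max(scores)
  trials <- cbind(data.frame(trial = seq_along(configs) - 1L,
                             is_default = seq_along(configs) == 1L),
                  do.call(rbind, lapply(configs, as.data.frame)),
                  validation_f1 = scores)
  list(best = configs[[best_i]], validation_f1 = scores[best_i], trials = trials)
}

#' Run the classifier benchmark on one train/test split
#'
#' Fits every spec on the training partition and evaluates support-weighted
#' F1 on the test partition. Only t = 1 datasets are accepted: the
#' non-neural classifiers consume flattened single-TR ROI vectors. The tuned
#' gradient-boosting spec is tuned on the fly (on the training partition
#' only) unless its hyperparameters are supplied.
#'
#' @param split an `rd_split` with `t = 1` datasets.
#' @param specs list of [classifier_spec()]; default full 11-model roster.
#' @param seed integer seed; the run is deterministic given the seed.
#' @param tune_space [search_space()] used for `gradient_boosting_tuned`.
#' @return data.frame with one row per spec (model, family, weighted_f1,
#'   fit_seconds); full `eval_report`s in the `reports` attribute.
#' @export
run_benchmark <- function(split, specs = default_classifier_specs(), seed = 1L,
                          tune_space = search_space()) {
  stopifnot(inherits(split, "rd_split"))
  if (split$train$t != 1L) stop("run_benchmark requires t = 1 datasets")
  xtr <- flatten_samples(split$train$x); ytr <- split$train$y
  xte <- flatten_samples(split$test$x); yte <- split$test$y
  n_classes <- length(split$train$class_names)
  rows <- vector("list", length(specs))
  reports <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    if (is.character(spec)) spec <- classifier_spec(spec)
    if (spec$name == "gradient_boosting_tuned" &&
        length(spec$hyperparameters) == 0) {
      tuned <- tune_gradient_boosting(split, tune_space, seed = seed)
      spec$hyperparameters <- tuned$best
    }
    tm <- system.time({
      model <- fit_classifier(spec, xtr, ytr, n_classes = n_classes,
                              seed = seed + i)
      set.seed(seed + i)  # covers the dummy's stochastic predictions
      pred <- predict(model, xte)
    })
    rep <- weighted_f1(yte, pred, classes = 0:(n_classes - 1L))
    reports[[i]] <- rep
    rows[[i]] <- data.frame(model = spec$name, family = spec$family,
                            weighted_f1 = rep$weighted_f1,
                            fit_seconds = unname(tm["elapsed"]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(reports) <- out$model
  attr(out, "reports") <- reports
  out
}
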