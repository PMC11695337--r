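# Shared fixtures, built in code at test time.

# Plain planted-signal tabular dataset wrapped as an rd_dataset (t = 1):
# class-1 samples get `effect` added on the `informative` ROIs.
toy_dataset <- function(seed, n = 500, n_rois = 10, informative = integer(0),
                        effect = 1, n_classes = 2) {
  set.seed(seed)
  y <- sample(0:(n_classes - 1L), n, replace = TRUE)
  x <- matrix(stats::rnorm(n * n_rois), n, n_rois)
  for (r in informative) x[, r] <- x[, r] + effect * (y == 1L)
  arr <- array(0, c(n, n_rois, 1L))
  arr[, , 1L] <- x
  structure(list(x = arr, y = as.integer(y),
                 class_names = as.character(seq_len(n_classes)), t = 1L,
                 problem = "toy",
                 provenance = data.frame(task = "toy", session = 1L)[rep(1, n), ]),
            class = "rd_dataset")
}

# Balanced labeled dataset with pure-noise features, for dummy-baseline checks.
noise_dataset <- function(seed, proportions, n_total, n_rois = 4L) {
  set.seed(seed)
  n_per <- round(proportions * n_total)
  y <- rep(seq_along(proportions) - 1L, n_per)
  n <- length(y)
  arr <- array(stats::rnorm(n * n_rois), c(n, n_rois, 1L))
  structure(list(x = arr, y = as.integer(y),
                 class_names = as.character(seq_along(proportions)), t = 1L,
                 problem = "noise",
                 provenance = data.frame(task = "x", session = 1L)[rep(1, n), ]),
            class = "rd_dataset")
}

# Mean dummy-baseline weighted F1 over `n_seeds` independent draws of the
# target setup: n_total labeled noise samples, stratified 90:10 split,
# prior-sampling dummy fitted on train and scored on test.
simulate_dummy_f1 <- function(proportions, n_total, n_seeds = 200,
                              seed_base = 0L) {
  vals <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    ds <- noise_dataset(seed_base + s, proportions, n_total)
    sp <- split_train_test(ds, 0.9, seed = seed_base + s, stratified = TRUE)
    m <- fit_classifier("dummy", roidecode:::flatten_samples(sp$train$x),
                        sp$train$y, n_classes = length(proportions),
                        seed = seed_base + s)
    set.seed(seed_base + s + 104729L)
    pred <- predict(m, roidecode:::flatten_samples(sp$test$x))
    vals[s] <- weighted_f1(sp$test$y, pred,
                           classes = seq_along(proportions) - 1L)$weighted_f1
  }
  mean(vals)
}

# Independent brute-force weighted-F1 oracle: explicit confusion-matrix loop,
# sharing no code with the package implementation.
oracle_weighted_f1 <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  total <- 0
  wsum <- 0
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    w <- tp + fn
    total <- total + w * f1
    wsum <- wsum + w
  }
  total / wsum
}

# Exhaustive subset-enumeration oracle for the zeroing perturbation
# importance: averages the flip score over all k-subsets containing each ROI.
oracle_perturb_exhaustive <- function(model, x, k) {
  n_rois <- dim(x)[2]
  subsets <- utils::combn(n_rois, k, simplify = FALSE)
  base_pred <- predict_labels(model, x)
  buffers <- rep(list(numeric(0)), n_rois)
  for (R in subsets) {
    s <- mean(predict_labels(model, zero_perturbation(x, R)) != base_pred)
    for (r in R) buffers[[r]] <- c(buffers[[r]], s)
  }
  vapply(buffers, mean, numeric(1))
}

dataset_subset_for_test <- function(ds, idx) roidecode:::dataset_subset(ds, idx)

# Small study -> phase series for end-to-end problems without 116-ROI cost:
# custom informative map on a compact atlas.
small_study_series <- function(seed, n_rois = 24L, effect = 0.8,
                               n_sessions = 1L, include_rest = TRUE,
                               n_trials = 60L) {
  inf <- list(
    encoding = list(GLO = 1:6, LOC = c(1:3, 7:9), SEM = c(10:15),
                    PHO = c(10:12, 16:18)),
    retrieval = list(GLO = c(19:21, 1:3), LOC = c(19:21, 4:6),
                     SEM = c(22:24, 10:12), PHO = c(22:24, 13:15))
  )
  cfg <- generator_config(n_rois = n_rois, seed = seed, effect_size = effect,
                          informative_rois = inf, n_sessions = n_sessions,
                          include_rest = include_rest, n_trials = n_trials)
  segment_study(generate_study(cfg), base_seed = seed)
}
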