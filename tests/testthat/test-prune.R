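test_that("split counts identify a stump's single split and sum over all nodes", {
  ds <- toy_dataset(1, n = 400, n_rois = 6, informative = 5, effect = 3)
  x <- roidecode:::flatten_samples(ds$x)
  colnames(x) <- sprintf("f%04d", 1:6)
  stump <- fit_classifier(classifier_spec("gradient_boosting",
                                          list(nrounds = 1L, num_leaves = 2L)),
                          x, ds$y, n_classes = 2, seed = 1)
  counts <- split_counts(stump)
  expect_equal(unname(counts["f0005"]), 2L)  # one stump per class in multi:softprob
  expect_equal(sum(counts[-5]), 0L)
  # counts sum equals the number of split nodes in an independent dump
  deep <- fit_classifier(classifier_spec("gradient_boosting", list(nrounds = 10L)),
                         x, ds$y, n_classes = 2, seed = 2)
  counts2 <- split_counts(deep)
  dump <- xgboost::xgb.dump(deep$fit$booster)
  n_split_nodes <- sum(grepl("\\[f", dump))
  expect_equal(sum(counts2), n_split_nodes)
  # non-tree models are rejected
  ridge <- fit_classifier("ridge", x, ds$y, n_classes = 2, seed = 1)
  expect_error(split_counts(ridge), "tree")
  expect_error(split_counts(list(a = 1)), "tree")
})

test_that("the pruning trace has the contracted loop structure", {
  ds <- toy_dataset(2, n = 300, n_rois = 8, informative = c(2, 5), effect = 1.5)
  dte <- toy_dataset(3, n = 120, n_rois = 8, informative = c(2, 5), effect = 1.5)
  tr <- prune_importance(ds, dte, gbm_factory(nrounds = 30), seed = 4)
  expect_s3_class(tr, "pruning_trace")
  expect_length(tr$z_scores, 7L)            # n_rois - 1 fit steps
  expect_setequal(tr$removal_order, 1:8)    # permutation incl. survivor
  expect_length(tr$removal_order, 8L)
  # buffer length equals the step at which the ROI left the model
  for (pos in seq_along(tr$removal_order)) {
    r <- tr$removal_order[pos]
    expect_length(tr$buffers[[r]], pos)
  }
  # step n covers exactly the ROIs not yet removed
  for (n in seq_along(tr$z_scores)) {
    expected_rois <- setdiff(1:8, tr$removal_order[seq_len(n - 1)])
    expect_setequal(as.integer(names(tr$z_scores[[n]])), expected_rois)
  }
  expect_length(tr$step_f1, 7L)
  expect_true(all(is.finite(tr$final_scores)))
  # z-scores have mean ~0 across surviving features at every step
  for (z in tr$z_scores) expect_lt(abs(mean(z)), 1e-10)
  # mean aggregation is available
  trm <- prune_importance(ds, dte, gbm_factory(nrounds = 30), seed = 4,
                          aggregate = "mean")
  expect_equal(trm$final_scores[tr$removal_order[1]],
               mean(trm$buffers[[tr$removal_order[1]]]))
})

test_that("a single strongly informative ROI is pruned first", {
  hits <- 0L
  for (s in 1:10) {
    ds <- toy_dataset(200 + s, n = 400, n_rois = 10, informative = 7, effect = 2)
    dte <- toy_dataset(300 + s, n = 100, n_rois = 10, informative = 7, effect = 2)
    tr <- prune_importance(ds, dte, gbm_factory(nrounds = 30), seed = s)
    if (tr$removal_order[1] == 7L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("the delta matrix exposes correlation compensation and masks removals", {
  set.seed(5)
  n <- 800
  y <- sample(0:1, n, replace = TRUE)
  x <- matrix(stats::rnorm(n * 10), n, 10)
  x[, 3] <- x[, 3] + 2.0 * y
  x[, 8] <- x[, 3] + stats::rnorm(n, sd = 0.05)  # near-perfect duplicate
  arr <- array(0, c(n, 10, 1)); arr[, , 1] <- x
  ds <- structure(list(x = arr, y = y, class_names = c("0", "1"), t = 1L,
                       problem = "dup",
                       provenance = data.frame(task = "x", session = 1)[rep(1, n), ]),
                  class = "rd_dataset")
  tr <- prune_importance(ds, ds, gbm_factory(nrounds = 40), seed = 6)
  D <- delta_matrix(tr)
  expect_equal(dim(D), c(8L, 10L))
  first <- tr$removal_order[1]
  expect_true(first %in% c(3L, 8L))
  twin <- setdiff(c(3L, 8L), first)
  expect_gt(D[1, twin], 0)           # twin takes over the removed ROI's role
  expect_true(is.na(D[1, first]))    # removed cells are masked
  removed <- attr(D, "removed")
  for (nstep in 1:8) {
    expect_setequal(which(removed[nstep, ]), tr$removal_order[seq_len(nstep)])
    expect_true(all(is.na(D[nstep, tr$removal_order[seq_len(nstep)]])))
  }
})

test_that("deltas of label-independent ROIs center on zero", {
  deltas <- numeric(0)
  for (s in 1:10) {
    ds <- toy_dataset(400 + s, n = 300, n_rois = 12, informative = 1, effect = 2)
    tr <- prune_importance(ds, ds, gbm_factory(nrounds = 20), seed = s)
    D <- delta_matrix(tr)
    noise_rois <- setdiff(1:12, 1)
    deltas <- c(deltas, D[1, noise_rois])
  }
  expect_lt(abs(mean(deltas, na.rm = TRUE)), 0.3)
})

test_that("pure-noise data give no fixed-index bias in final scores", {
  score_mat <- matrix(0, 12, 6)
  for (s in 1:12) {
    ds <- toy_dataset(600 + s, n = 250, n_rois = 6, informative = integer(0))
    tr <- prune_importance(ds, ds, gbm_factory(nrounds = 15), seed = s)
    score_mat[s, ] <- tr$final_scores
  }
  expect_lt(max(abs(colMeans(score_mat))), 0.5)
})
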