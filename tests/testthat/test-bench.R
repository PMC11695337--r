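test_that("the default roster produces one row per model with correct families", {
  ds <- toy_dataset(1, n = 600, n_rois = 12, informative = 1:3, effect = 1.2)
  sp <- split_train_test(ds, 0.9, seed = 2)
  bench <- run_benchmark(sp, seed = 3, tune_space = search_space(n_trials = 3))
  expect_equal(nrow(bench), 11L)
  expect_equal(bench$model[1], "dummy")
  expect_equal(bench$family[bench$model == "dummy"], "baseline")
  expect_equal(bench$family[bench$model == "random_forest"], "nonlinear")
  expect_equal(bench$family[bench$model == "lda"], "linear")
  expect_true(all(bench$weighted_f1 >= 0 & bench$weighted_f1 <= 1))
  reports <- attr(bench, "reports")
  expect_length(reports, 11L)
  expect_equal(sum(reports$dummy$per_class$support), length(sp$test$y))
  # informative features are learnable: the tree ensembles beat the dummy
  expect_gt(bench$weighted_f1[bench$model == "gradient_boosting"],
            bench$weighted_f1[bench$model == "dummy"] + 0.1)
})

test_that("the benchmark refuses temporal datasets and unknown models", {
  series <- small_study_series(2, include_rest = FALSE)
  ds6 <- assemble_problem(series, "ENC2", t = 6)
  sp6 <- split_train_test(ds6, 0.9, seed = 1)
  expect_error(run_benchmark(sp6, seed = 1), "t = 1")
  expect_error(classifier_spec("boosted_cnn"), "unknown classifier")
})

test_that("the dummy row tracks the analytic baseline of the test class mix", {
  ds <- noise_dataset(4, c(0.4, 0.4, 0.2), 2000)
  sp <- split_train_test(ds, 0.9, seed = 4)
  bench <- run_benchmark(sp, specs = list(classifier_spec("dummy")), seed = 9)
  props <- as.numeric(table(sp$test$y)) / length(sp$test$y)
  expect_lt(abs(bench$weighted_f1[1] - expected_dummy_f1(props)), 0.05)
})

test_that("no classifier shows skill on zero-effect data", {
  # average F1 over 5 seeds stays within 0.05 of the dummy's
  f1s <- matrix(0, 5, 11)
  for (s in 1:5) {
    ds <- toy_dataset(100 + s, n = 800, n_rois = 16, informative = integer(0))
    sp <- split_train_test(ds, 0.9, seed = s)
    bench <- run_benchmark(sp, seed = s, tune_space = search_space(n_trials = 2))
    f1s[s, ] <- bench$weighted_f1
  }
  means <- colMeans(f1s)
  expect_true(all(abs(means - means[1]) <= 0.05),
              info = paste(round(means, 3), collapse = " "))
})

test_that("random forest dominates ridge on an XOR-style ROI pair", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 600
    x <- matrix(stats::rnorm(n * 10), n, 10)
    a <- sample(c(-1, 1), n, replace = TRUE)
    b <- sample(c(-1, 1), n, replace = TRUE)
    x[, 1] <- a + 0.3 * stats::rnorm(n)
    x[, 2] <- b + 0.3 * stats::rnorm(n)
    y <- as.integer(a * b > 0)
    arr <- array(0, c(n, 10, 1)); arr[, , 1] <- x
    ds <- structure(list(x = arr, y = y, class_names = c("0", "1"), t = 1L,
                         problem = "xor",
                         provenance = data.frame(task = "x", session = 1)[rep(1, n), ]),
                    class = "rd_dataset")
    sp <- split_train_test(ds, 0.9, seed = s)
    bench <- run_benchmark(sp, specs = list(classifier_spec("ridge"),
                                            classifier_spec("random_forest")),
                           seed = s)
    if (bench$weighted_f1[2] > bench$weighted_f1[1]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("gradient-boosting tuning searches within bounds and never loses to the default", {
  ds <- toy_dataset(5, n = 500, n_rois = 10, informative = 1:2, effect = 1)
  sp <- split_train_test(ds, 0.9, seed = 5)
  tuned <- tune_gradient_boosting(sp, search_space(n_trials = 8), seed = 6,
                                  nrounds = 40)
  tr <- tuned$trials
  sampled <- tr[!tr$is_default, ]
  expect_true(all(sampled$lambda_l1 >= 1e-8 & sampled$lambda_l1 <= 10))
  expect_true(all(sampled$lambda_l2 >= 1e-8 & sampled$lambda_l2 <= 10))
  expect_true(all(sampled$num_leaves >= 2 & sampled$num_leaves <= 128))
  expect_true(all(sampled$feature_fraction >= 0.1 & sampled$feature_fraction <= 1))
  expect_true(all(sampled$bagging_fraction >= 0.1 & sampled$bagging_fraction <= 1))
  expect_true(all(sampled$bagging_freq >= 1 & sampled$bagging_freq <= 7))
  expect_gte(tuned$validation_f1, tr$validation_f1[tr$is_default])
  tuned2 <- tune_gradient_boosting(sp, search_space(n_trials = 8), seed = 6,
                                   nrounds = 40)
  expect_identical(tuned$trials, tuned2$trials)
  expect_identical(tuned$best, tuned2$best)
  expect_error(search_space(n_trials = 0), "n_trials")
})
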