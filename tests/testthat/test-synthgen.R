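test_that("a task session has the configured shape and event layout", {
  cfg <- generator_config(seed = 3)
  s <- generate_session(cfg, "GLO", seed = 11)
  expect_equal(nrow(s$ts$values), 116L)
  expect_equal(length(s$ts$roi_labels), 116L)
  expect_false(anyNA(s$ts$values))
  expect_equal(sum(s$events$phase == "encoding"), 60L)
  expect_equal(sum(s$events$phase == "retrieval"), 60L)
  for (ph in c("encoding", "retrieval")) {
    on <- s$events$onset[s$events$phase == ph]
    expect_true(all(diff(on) > 0))
  }
  expect_true(all(s$events$duration > 0))
  # series long enough to hold the last retrieval segment
  last_ret <- max(s$events$onset[s$events$phase == "retrieval"])
  expect_gte(ncol(s$ts$values), floor(last_ret / cfg$tr_seconds) + 7)
})

test_that("rest sessions are eventless and invalid inputs are rejected", {
  cfg <- generator_config(seed = 3)
  r <- generate_session(cfg, "REST", seed = 2)
  expect_equal(nrow(r$events), 0L)
  expect_gte(ncol(r$ts$values), 400L)
  expect_error(generate_session(cfg, "FOO", seed = 1), "unknown task")
  expect_error(generator_config(n_trials = 0), "n_trials")
  expect_error(generator_config(ar_coefficient = 1.0), "ar_coefficient")
  expect_error(generator_config(effect_size = -1), "effect_size")
})

test_that("generation is bit-identical under a repeated config and seed", {
  cfg <- generator_config(seed = 9)
  a <- generate_session(cfg, "SEM", seed = 21)
  b <- generate_session(cfg, "SEM", seed = 21)
  expect_identical(a$ts$values, b$ts$values)
  expect_identical(a$events, b$events)
  st1 <- generate_study(generator_config(seed = 5, n_rois = 48))
  st2 <- generate_study(generator_config(seed = 5, n_rois = 48))
  expect_identical(st1$sessions[[3]]$ts$values, st2$sessions[[3]]$ts$values)
})

test_that("the planted activation is detectable at alpha = 0.01 in >= 95% of runs", {
  # Monte-Carlo power oracle on the stated Gaussian AR(1) model: in-segment
  # TRs of one informative ROI vs the same count of rest TRs.
  inf <- list(encoding = list(GLO = 1L), retrieval = list())
  cfg <- generator_config(n_rois = 3, informative_rois = inf, seed = 1,
                          effect_size = 0.8)
  hits <- 0L
  n_runs <- 200L
  for (run in seq_len(n_runs)) {
    s <- generate_session(cfg, "GLO", seed = run)
    segs <- extract_phase_segments(s$ts, s$events, "encoding")
    task_vals <- unlist(lapply(segs, function(g) g$values[1, ]))
    r <- generate_session(cfg, "REST", seed = run + 50000L)
    rest_vals <- r$ts$values[1, 1:400]
    p <- stats::t.test(task_vals, rest_vals)$p.value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("AR(1) noise is stationary with the configured lag-1 autocorrelation", {
  cfg <- generator_config(n_rois = 1, rest_trs = 10000L, seed = 2,
                          informative_rois = list(encoding = list(), retrieval = list()))
  r <- generate_session(cfg, "REST", seed = 13)
  x <- r$ts$values[1, ]
  ac1 <- stats::cor(x[-1], x[-length(x)])
  expect_lt(abs(ac1 - 0.4), 0.05)
  expect_lt(abs(stats::sd(x) - 1), 0.1)
})

test_that("duplicate injection reproduces the closed-form correlation", {
  cfg <- generator_config(n_rois = 4, rest_trs = 4000L, seed = 7,
                          informative_rois = list(encoding = list(), retrieval = list()))
  r <- generate_session(cfg, "REST", seed = 5)
  # exact copy
  t0 <- inject_duplicates(r$ts, list(c(1, 2, 0)))
  expect_identical(t0$values[1, ], t0$values[2, ])
  expect_identical(t0$values[3, ], r$ts$values[3, ])
  expect_identical(dim(t0$values), dim(r$ts$values))
  # unit-variance source + sd 0.2 noise: cor = 1/sqrt(1 + 0.04)
  set.seed(31)
  tn <- inject_duplicates(r$ts, list(c(1, 2, 0.2)))
  expect_lt(abs(stats::cor(tn$values[1, ], tn$values[2, ]) - 1 / sqrt(1.04)), 0.02)
  expect_error(inject_duplicates(r$ts, list(c(1, 1, 0))), "differ")
  expect_error(inject_duplicates(r$ts, list(c(1, 9, 0))), "range")
})

test_that("a study yields one series per task/session plus rest, with ground truth", {
  cfg <- generator_config(seed = 5, n_rois = 48, n_sessions = 1)
  st <- generate_study(cfg)
  expect_length(st$sessions, 5L)  # 4 tasks + rest
  expect_setequal(vapply(st$sessions, `[[`, "", "task"),
                  c("GLO", "LOC", "SEM", "PHO", "REST"))
  expect_identical(st$ground_truth$informative_rois, cfg$informative_rois)
  expect_identical(st$ground_truth$effect_size, cfg$effect_size)
  cfg2 <- generator_config(seed = 5, n_rois = 48, n_sessions = 2)
  expect_length(generate_study(cfg2)$sessions, 10L)
})

test_that("class separability is monotone in effect size on matched seeds", {
  f1_at <- function(effect, seed) {
    series <- small_study_series(seed, effect = effect, include_rest = FALSE)
    ds <- assemble_problem(series, "ENC2", t = 1)
    sp <- split_train_test(ds, 0.9, seed = seed)
    m <- fit_classifier(classifier_spec("gradient_boosting", list(nrounds = 50L)),
                        roidecode:::flatten_samples(sp$train$x), sp$train$y,
                        n_classes = 2, seed = seed)
    weighted_f1(sp$test$y, predict(m, roidecode:::flatten_samples(sp$test$x)))$weighted_f1
  }
  wins <- 0L
  for (seed in 1:10) {
    if (f1_at(1.5, seed) >= f1_at(0.5, seed)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
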