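count_layers <- function(model, type) {
  sum(vapply(model$layers, function(l) l$type == type, logical(1)))
}

test_that("the CNN has three length-3 convolutions in the stated order", {
  m <- build_cnn(cnn_config(n_classes = 3, channels = c(8, 8, 16)), t = 6,
                 n_rois = 20, seed = 1)
  convs <- Filter(function(l) l$type == "conv1d", m$layers)
  expect_length(convs, 3L)
  expect_true(all(vapply(convs, `[[`, integer(1), "k") == 3L))
  types <- vapply(m$layers, `[[`, "", "type")
  conv_pos <- which(types == "conv1d")
  pool_pos <- which(types == "maxpool1d")
  lin_pos <- which(types == "linear")
  drop_pos <- which(types == "dropout")
  expect_true(conv_pos[1] < conv_pos[2] && conv_pos[2] < pool_pos)
  expect_true(pool_pos < conv_pos[3] && conv_pos[3] < drop_pos)
  expect_true(drop_pos < lin_pos)
  expect_error(build_cnn(cnn_config(2), t = 1), "t = 6")
  expect_error(cnn_config(2, dropout = 0.15), "dropout")
  expect_error(cnn_config(2, learning_rate = 0.01), "learning_rate")
})

test_that("the CNN forward pass yields a probability simplex over classes", {
  m <- build_cnn(cnn_config(n_classes = 4, channels = c(8, 8, 16)), t = 6,
                 n_rois = 15, seed = 2)
  x <- array(stats::rnorm(7 * 15 * 6), c(7, 15, 6))
  p <- predict(m, x, type = "prob")
  expect_equal(dim(p), c(7L, 4L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  cls <- predict(m, x, type = "class")
  expect_true(all(cls %in% 0:3))
})

test_that("ResNet depth follows the 6k+2 rule with compliant blocks", {
  for (case in list(c(14, 2), c(20, 3), c(32, 5), c(56, 9))) {
    m <- build_resnet(resnet_config(case[1], n_classes = 2, widths = c(2, 2, 4)),
                      t = 1, n_rois = 12, seed = 1)
    blocks <- Filter(function(l) l$type == "resblock", m$layers)
    expect_length(blocks, 3L * case[2])
    # stage membership: widths change twice via stride-2 blocks
    strided <- sum(vapply(blocks, function(b) b$stride == 2L, logical(1)))
    expect_equal(strided, 2L)
    for (b in blocks) {
      expect_equal(b$conv1$k, 3L)
      expect_equal(b$conv2$k, 3L)
      expect_equal(b$bn1$type, "bn")
      expect_equal(b$bn2$type, "bn")
      if (!is.null(b$shortcut)) expect_equal(b$shortcut$conv$k, 1L)
    }
  }
  expect_error(resnet_config(15), "size")
  expect_error(resnet_config(14, weight_decay = 0.2), "weight_decay")
})

test_that("ResNet forward pass handles both input widths", {
  m6 <- build_resnet(resnet_config(14, n_classes = 3, widths = c(4, 4, 8)),
                     t = 6, n_rois = 20, seed = 3)
  p6 <- predict(m6, array(stats::rnorm(5 * 20 * 6), c(5, 20, 6)), type = "prob")
  expect_true(all(abs(rowSums(p6) - 1) < 1e-6))
  m1 <- build_resnet(resnet_config(14, n_classes = 2, widths = c(4, 4, 8)),
                     t = 1, n_rois = 20, seed = 3)
  p1 <- predict(m1, array(stats::rnorm(5 * 20 * 1), c(5, 20, 1)), type = "prob")
  expect_true(all(abs(rowSums(p1) - 1) < 1e-6))
  expect_error(build_resnet(resnet_config(14, n_classes = 2), t = 3), "t must be")
})

test_that("early stopping fires exactly per the patience rule", {
  expect_equal(early_stop_epoch(c(1.0, .9, .9, .9, .9, .9, .9), patience = 5), 7L)
  expect_equal(early_stop_epoch(c(1, .9, .8, .7), patience = 5), 4L)  # no stop
  expect_equal(early_stop_epoch(c(1, 1, 1), patience = 2), 3L)
  expect_equal(early_stop_epoch(c(5, 4, 4.5, 3, 3.1, 3.2, 3.3, 3.4, 3.5),
                                patience = 5), 9L)
  expect_equal(early_stop_epoch(c(5, 4, 4.5, 3, 3.1, 3.2, 3.3, 3.4, 3.5, 3.6),
                                patience = 5), 9L)  # stops; later epochs unreachable
  expect_error(train_config(patience = 0), "patience")
  expect_error(train_config(max_epochs = 0), "max_epochs")
})

test_that("training respects the epoch cap and is deterministic by seed", {
  ds <- toy_dataset(9, n = 120, n_rois = 8, informative = 1:2, effect = 2)
  # lift to t = 6 by repeating the single TR with noise
  x6 <- array(stats::rnorm(120 * 8 * 6, sd = 0.1), c(120, 8, 6))
  for (tt in 1:6) x6[, , tt] <- x6[, , tt] + ds$x[, , 1]
  ds6 <- structure(list(x = x6, y = ds$y, class_names = ds$class_names, t = 6L,
                        problem = "toy6", provenance = ds$provenance),
                   class = "rd_dataset")
  sp <- split_train_test(ds6, 0.9, seed = 1)
  m <- build_cnn(cnn_config(2, channels = c(4, 4, 8)), t = 6, n_rois = 8, seed = 4)
  tr <- train_model(m, sp, train_config(max_epochs = 12, seed = 4))
  expect_lte(nrow(tr$history), 12L)
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in% names(tr$history)))
  tr2 <- train_model(m, sp, train_config(max_epochs = 12, seed = 4))
  expect_identical(tr$history, tr2$history)
})

test_that("relabeling classes yields the complementary decision function", {
  # same seed, labels swapped: predictions on held-out data swap accordingly
  ds <- toy_dataset(12, n = 300, n_rois = 10, informative = 1:3, effect = 3)
  x6 <- array(0, c(300, 10, 6))
  for (tt in 1:6) x6[, , tt] <- ds$x[, , 1] * (tt / 6)
  mk <- function(y) structure(list(x = x6, y = y, class_names = c("a", "b"),
                                   t = 6L, problem = "swap",
                                   provenance = ds$provenance),
                              class = "rd_dataset")
  spA <- split_train_test(mk(ds$y), 0.9, seed = 2)
  spB <- split_train_test(mk(1L - ds$y), 0.9, seed = 2)
  m <- build_cnn(cnn_config(2, channels = c(4, 4, 8)), t = 6, n_rois = 10, seed = 6)
  mA <- train_model(m, spA, train_config(max_epochs = 40, seed = 6))$model
  mB <- train_model(m, spB, train_config(max_epochs = 40, seed = 6))$model
  # common held-out probe set: both models should disagree on (almost) all of it
  probe <- toy_dataset(13, n = 60, n_rois = 10, informative = 1:3, effect = 3)
  p6 <- array(0, c(60, 10, 6))
  for (tt in 1:6) p6[, , tt] <- probe$x[, , 1] * (tt / 6)
  expect_gte(mean(predict(mA, p6) == (1L - predict(mB, p6))), 0.9)
})
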