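#' 1D CNN configuration
#'
#' Hyperparameters restricted to the tuning sets used for this architecture:
#' dropout in \{0, 0.1, 0.2, 0.3\}, learning rate in
#' \{0.0001, 0.0005, 0.001\}, batch size 32. Channel widths default to
#' 64/64/128; smaller widths are appropriate for CPU-scale experiments.
#'
#' @param n_classes number of output classes.
#' @param dropout dropout probability before the final linear layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param channels widths of the three convolutional layers.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(n_classes, dropout = 0.1, learning_rate = 0.001,
                       batch_size = 32L, channels = c(64L, 64L, 128L)) {
  if (!dropout %in% c(0, 0.1, 0.2, 0.3)) stop("dropout must be in {0, 0.1, 0.2, 0.3}")
  if (!learning_rate %in% c(1e-4, 5e-4, 1e-3)) {
    stop("learning_rate must be in {0.0001, 0.0005, 0.001}")
  }
  stopifnot(length(channels) == 3L, n_classes >= 2L)
  structure(list(n_classes = as.integer(n_classes), dropout = dropout,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 channels = as.integer(channels)), class = "cnn_config")
}

#' ResNet configuration
#'
#' Sizes follow the 6k+2 stage-depth rule with k residual blocks per stage
#' (14 -> 2, 20 -> 3, 32 -> 5, 56 -> 9). Other hyperparameters are restricted
#' to their tuning sets.
#'
#' @param size total depth, one of 14, 20, 32, 56.
#' @param n_classes number of output classes.
#' @param batch_size one of 32, 64, 128, 256.
#' @param learning_rate one of 0.0001, 0.0005, 0.001, 0.005, 0.01.
#' @param dropout one of 0, 0.1, 0.2, 0.3 (before the final linear layer).
#' @param weight_decay one of 0.01, 0.05, 0.1 (L2 on conv/linear weights).
#' @param widths channel widths of the three stages (CIFAR convention
#'   16/32/64; reduce for desk-scale runs).
#' @return object of class `resnet_config`.
#' @export
resnet_config <- function(size = 14L, n_classes = 2L, batch_size = 32L,
                          learning_rate = 0.001, dropout = 0.0,
                          weight_decay = 0.01, widths = c(16L, 32L, 64L)) {
  if (!size %in% c(14L, 20L, 32L, 56L)) stop("size must be one of 14, 20, 32, 56")
  if (!batch_size %in% c(32L, 64L, 128L, 256L)) {
    stop("batch_size must be one of 32, 64, 128, 256")
  }
  if (!learning_rate %in% c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2)) {
    stop("learning_rate outside the tuning set")
  }
  if (!dropout %in% c(0, 0.1, 0.2, 0.3)) stop("dropout must be in {0, 0.1, 0.2, 0.3}")
  if (!weight_decay %in% c(0.01, 0.05, 0.1)) {
    stop("weight_decay must be one of 0.01, 0.05, 0.1")
  }
  stopifnot(length(widths) == 3L)
  structure(list(size = as.integer(size), n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size), learning_rate = learning_rate,
                 dropout = dropout, weight_decay = weight_decay,
                 widths = as.integer(widths),
                 blocks_per_stage = (as.integer(size) - 2L) %/% 6L),
            class = "resnet_config")
}

#' Build the 1D convolutional classifier
#'
#' Architecture (in order): two 1D convolutional layers, 1D max pooling,
#' another 1D convolution, a linear layer with dropout, and a final softmax.
#' All convolutions use kernels of length 3 and slide along the time axis
#' with the ROIs as input channels, so every filter can combine any subset of
#' brain regions at each time step. Requires t = 6 temporal samples.
#'
#' @param config a [cnn_config()].
#' @param t temporal extent of the input samples; must be 6.
#' @param n_rois number of ROIs (input channels).
#' @param seed seed for weight initialization.
#' @return object of class `rd_nn`.
#' @export
build_cnn <- function(config, t = 6L, n_rois = 116L, seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  if (t != 6L) stop("the CNN consumes temporal samples only (t = 6)")
  set.seed(seed)
  ch <- config$channels
  t_pool <- t %/% 2L
  layers <- list(
    nn_conv1d(n_rois, ch[1]), nn_relu(),
    nn_conv1d(ch[1], ch[2]), nn_relu(),
    nn_maxpool1d(2L),
    nn_conv1d(ch[2], ch[3]), nn_relu(),
    nn_flatten(),
    nn_dropout(config$dropout),
    nn_linear(ch[3] * t_pool, config$n_classes)
  )
  structure(list(arch = "cnn", layers = layers, config = config,
                 n_rois = as.integer(n_rois), t = as.integer(t),
                 n_classes = config$n_classes), class = "rd_nn")
}

#' Build a residual-network classifier
#'
#' The input is treated as a single-channel 2D image of shape
#' `n_rois x t`, with ROIs kept in atlas order so that 3x3 kernels mix
#' atlas-adjacent regions (left/right homologs sit on neighboring rows).
#' Structure: input 3x3 convolution with batch norm, three stages of k
#' residual blocks (size = 6k + 2; stages 2 and 3 downsample by stride 2),
#' global average pooling, dropout, and a linear logit layer. Each residual
#' block holds two 3x3 convolutions, a batch normalization after each, and a
#' shortcut connection (1x1 convolution where shape changes).
#'
#' @param config a [resnet_config()].
#' @param t temporal extent of the inputs (1 or 6); with t = 1 the 3x3
#'   kernels run over a zero-padded single-column image.
#' @param n_rois number of ROIs (image height).
#' @param seed seed for weight initialization.
#' @return object of class `rd_nn`.
#' @export
build_resnet <- function(config, t = 1L, n_rois = 116L, seed = 1L) {
  stopifnot(inherits(config, "resnet_config"))
  if (!t %in% c(1L, 6L)) stop("t must be 1 or 6")
  set.seed(seed)
  w <- config$widths
  k <- config$blocks_per_stage
  layers <- list(nn_conv2d(1L, w[1]), nn_bn(w[1]), nn_relu())
  for (i in seq_len(k)) layers <- c(layers, list(nn_resblock(w[1], w[1], 1L)))
  layers <- c(layers, list(nn_resblock(w[1], w[2], 2L)))
  for (i in seq_len(k - 1L)) layers <- c(layers, list(nn_resblock(w[2], w[2], 1L)))
  layers <- c(layers, list(nn_resblock(w[2], w[3], 2L)))
  for (i in seq_len(k - 1L)) layers <- c(layers, list(nn_resblock(w[3], w[3], 1L)))
  layers <- c(layers, list(nn_avgpool_global(), nn_dropout(config$dropout),
                           nn_linear(w[3], config$n_classes)))
  structure(list(arch = "resnet", layers = layers, config = config,
                 n_rois = as.integer(n_rois), t = as.integer(t),
                 n_classes = config$n_classes), class = "rd_nn")
}

# Internal: sample array (n, rois, t) -> network input
nn_input <- function(model, x) {
  if (model$arch == "cnn") return(x)  # (batch, channels = rois, time)
  d <- dim(x)
  xi <- array(0, c(d[1], 1L, d[2], d[3]))
  xi[, 1L, , ] <- x
  xi
}

#' Forward pass returning class probabilities or hard labels
#'
#' @param object an `rd_nn` model.
#' @param newdata `n x rois x t` sample array.
#' @param type `"class"` (0-based hard labels) or `"prob"`.
#' @param batch_size evaluation chunk size.
#' @param ... unused.
#' @export
predict.rd_nn <- function(object, newdata, type = c("class", "prob"),
                          batch_size = 256L, ...) {
  type <- match.arg(type)
  n <- dim(newdata)[1]
  probs <- matrix(0, n, object$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- nn_input(object, newdata[idx, , , drop = FALSE])
    out <- nn_forward(object$layers, xb, train = FALSE)
    probs[idx, ] <- softmax_rows(out$out)
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' Training protocol configuration
#'
#' Adam optimization for up to `max_epochs` epochs with early stopping when
#' the validation loss fails to improve for `patience` consecutive epochs,
#' and a scheduler that multiplies the learning rate by `lr_factor` after
#' `lr_patience` consecutive plateau epochs. The best-validation-loss weights
#' are restored at the end.
#'
#' @param max_epochs maximum training epochs (default 100).
#' @param patience early-stopping patience in epochs (default 5).
#' @param lr_factor plateau learning-rate reduction factor (default 0.1).
#' @param lr_patience plateau patience in epochs (default 3).
#' @param seed seed controlling initialization, shuffling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 100L, patience = 5L, lr_factor = 0.1,
                         lr_patience = 3L, seed = 1L) {
  if (patience < 1L) stop("patience must be >= 1")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 seed = as.integer(seed)), class = "train_config")
}

#' Early-stopping rule on a validation-loss sequence
#'
#' Returns the 1-based epoch after which training stops: the first epoch at
#' which the validation loss has failed to improve (strictly decrease below
#' the running best) for `patience` consecutive epochs, or the sequence
#' length if that never happens. The training loop applies exactly this rule
#' epoch by epoch.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience consecutive non-improving epochs tolerated.
#' @return integer stopping epoch.
#' @export
early_stop_epoch <- function(val_losses, patience = 5L) {
  best <- Inf
  streak <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) return(e)
    }
  }
  length(val_losses)
}

#' Train a neural model
#'
#' Carves a stratified 80:20 fit/validation sub-split out of the training
#' partition, trains with Adam and minibatches, applies the plateau scheduler
#' and the early-stopping rule of [train_config()], and restores the weights
#' of the best validation epoch.
#'
#' @param model an `rd_nn` from [build_cnn()] or [build_resnet()].
#' @param split an `rd_split` whose datasets match the model's t.
#' @param tc a [train_config()].
#' @return list with `model` (fitted) and `history` (data.frame of epoch,
#'   train_loss, val_loss, lr).
#' @export
train_model <- function(model, split, tc = train_config()) {
  stopifnot(inherits(model, "rd_nn"), inherits(split, "rd_split"))
  if (split$train$t != model$t) stop("split t does not match the model's input t")
  inner <- split_train_test(split$train, ratio = 0.8, seed = tc$seed,
                            stratified = TRUE)
  if (length(inner$train$y) == 0 || length(inner$test$y) == 0) {
    stop("empty fit or validation set")
  }
  xf <- inner$train$x; yf <- inner$train$y
  xv <- nn_input(model, inner$test$x); yv <- inner$test$y
  layers <- model$layers
  wd <- if (!is.null(model$config$weight_decay)) model$config$weight_decay else 0
  bs <- model$config$batch_size
  lr <- model$config$learning_rate
  set.seed(tc$seed)
  pvec <- unlist(nn_get_params(layers))
  opt <- adam_init(length(pvec))
  best_loss <- Inf
  best_layers <- layers
  es_streak <- 0L
  lr_streak <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  n_fit <- length(yf)
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample.int(n_fit)
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n_fit, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n_fit)]
      xb <- nn_input(model, xf[idx, , , drop = FALSE])
      fwd <- nn_forward(layers, xb, train = TRUE)
      layers <- fwd$layers
      loss <- ce_loss(fwd$out, yf[idx])
      grads <- nn_backward(layers, fwd$caches, loss$dlogits)
      skel <- nn_get_params(layers)
      pvec <- unlist(skel)
      gvec <- unlist(grads)
      if (wd > 0) gvec <- gvec + wd * pvec
      stepped <- adam_step(opt, pvec, gvec, lr)
      opt <- stepped$state
      layers <- nn_set_params(layers, utils::relist(stepped$pvec, skel))
      epoch_loss <- epoch_loss + loss$loss
      n_batches <- n_batches + 1L
    }
    val_out <- nn_forward(layers, xv, train = FALSE)
    val_loss <- ce_loss(val_out$out, yv)$loss
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = epoch_loss / n_batches,
                                   val_loss = val_loss, lr = lr))
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_layers <- layers  # snapshot includes batch-norm running stats
      es_streak <- 0L
      lr_streak <- 0L
    } else {
      es_streak <- es_streak + 1L
      lr_streak <- lr_streak + 1L
      if (lr_streak >= tc$lr_patience) {
        lr <- lr * tc$lr_factor
        lr_streak <- 0L
      }
      if (es_streak >= tc$patience) break
    }
  }
  model$layers <- best_layers
  list(model = model, history = hist)
}
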