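# Minimal neural-network layer framework: explicit forward/backward matrix
# code for 1D/2D convolution (im2col), batch normalization, max/average
# pooling, dropout and dense layers, plus Adam. Written against base R so the
# package carries no deep-learning runtime dependency.
#
# Conventions: 1D inputs are (batch, channels, time); 2D inputs are
# (batch, channels, height, width). All layer params are matrices or plain
# vectors so the whole parameter set round-trips through unlist()/relist().

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

nn_conv1d <- function(in_ch, out_ch, k = 3L, pad = 1L) {
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, k = k, pad = pad,
       params = list(W = he_init(in_ch * k, out_ch, in_ch * k), b = rep(0, out_ch)))
}

nn_conv2d <- function(in_ch, out_ch, k = 3L, pad = 1L, stride = 1L) {
  list(type = "conv2d", in_ch = in_ch, out_ch = out_ch, k = k, pad = pad,
       stride = stride,
       params = list(W = he_init(in_ch * k * k, out_ch, in_ch * k * k),
                     b = rep(0, out_ch)))
}

nn_bn <- function(n_ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", n_ch = n_ch, eps = eps, momentum = momentum,
       running_mean = rep(0, n_ch), running_var = rep(1, n_ch),
       params = list(gamma = rep(1, n_ch), beta = rep(0, n_ch)))
}

nn_relu <- function() list(type = "relu", params = list())
nn_maxpool1d <- function(size = 2L) list(type = "maxpool1d", size = size, params = list())
nn_dropout <- function(p) list(type = "dropout", p = p, params = list())
nn_flatten <- function() list(type = "flatten", params = list())
nn_avgpool_global <- function() list(type = "avgpool", params = list())

nn_linear <- function(in_dim, out_dim) {
  list(type = "linear", in_dim = in_dim, out_dim = out_dim,
       params = list(W = he_init(in_dim, out_dim, in_dim), b = rep(0, out_dim)))
}

nn_resblock <- function(in_ch, out_ch, stride = 1L) {
  shortcut <- if (stride != 1L || in_ch != out_ch) {
    list(conv = nn_conv2d(in_ch, out_ch, k = 1L, pad = 0L, stride = stride),
         bn = nn_bn(out_ch))
  } else NULL
  list(type = "resblock", in_ch = in_ch, out_ch = out_ch, stride = stride,
       conv1 = nn_conv2d(in_ch, out_ch, k = 3L, pad = 1L, stride = stride),
       bn1 = nn_bn(out_ch),
       conv2 = nn_conv2d(out_ch, out_ch, k = 3L, pad = 1L, stride = 1L),
       bn2 = nn_bn(out_ch),
       shortcut = shortcut)
}

# ---- conv1d ----------------------------------------------------------------

conv1d_fwd <- function(layer, x) {
  d <- dim(x); B <- d[1]; C <- d[2]; T <- d[3]
  k <- layer$k; pad <- layer$pad
  Tp <- T + 2L * pad
  Xp <- array(0, c(B, C, Tp))
  Xp[, , pad + seq_len(T)] <- x
  T_out <- Tp - k + 1L
  M <- matrix(0, B * T_out, C * k)
  for (j in seq_len(k)) {
    sub <- Xp[, , j:(j + T_out - 1L), drop = FALSE]
    M[, (j - 1L) * C + seq_len(C)] <- matrix(aperm(sub, c(1, 3, 2)), B * T_out, C)
  }
  out_mat <- sweep(M %*% layer$params$W, 2, layer$params$b, "+")
  out <- aperm(array(out_mat, c(B, T_out, layer$out_ch)), c(1, 3, 2))
  list(out = out, cache = list(M = M, B = B, C = C, T = T, T_out = T_out))
}

conv1d_bwd <- function(layer, cache, dout) {
  B <- cache$B; C <- cache$C; T <- cache$T; T_out <- cache$T_out
  k <- layer$k; pad <- layer$pad
  dmat <- matrix(aperm(dout, c(1, 3, 2)), B * T_out, layer$out_ch)
  dW <- crossprod(cache$M, dmat)
  db <- colSums(dmat)
  dM <- dmat %*% t(layer$params$W)
  dXp <- array(0, c(B, C, T + 2L * pad))
  for (j in seq_len(k)) {
    blk <- aperm(array(dM[, (j - 1L) * C + seq_len(C)], c(B, T_out, C)), c(1, 3, 2))
    idx <- j:(j + T_out - 1L)
    dXp[, , idx] <- dXp[, , idx, drop = FALSE] + blk
  }
  list(dx = dXp[, , pad + seq_len(T), drop = FALSE], grads = list(W = dW, b = db))
}

# ---- conv2d ----------------------------------------------------------------

conv2d_fwd <- function(layer, x) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  k <- layer$k; pad <- layer$pad; s <- layer$stride
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Xp <- array(0, c(B, C, Hp, Wp))
  Xp[, , pad + seq_len(H), pad + seq_len(W)] <- x
  H_out <- (Hp - k) %/% s + 1L
  W_out <- (Wp - k) %/% s + 1L
  M <- matrix(0, B * H_out * W_out, C * k * k)
  for (j in seq_len(k)) {
    ws <- j + (seq_len(W_out) - 1L) * s
    for (i in seq_len(k)) {
      hs <- i + (seq_len(H_out) - 1L) * s
      sub <- Xp[, , hs, ws, drop = FALSE]
      q <- ((i - 1L) + (j - 1L) * k) * C + seq_len(C)
      M[, q] <- matrix(aperm(sub, c(1, 3, 4, 2)), B * H_out * W_out, C)
    }
  }
  out_mat <- sweep(M %*% layer$params$W, 2, layer$params$b, "+")
  out <- aperm(array(out_mat, c(B, H_out, W_out, layer$out_ch)), c(1, 4, 2, 3))
  list(out = out,
       cache = list(M = M, B = B, C = C, H = H, W = W,
                    H_out = H_out, W_out = W_out))
}

conv2d_bwd <- function(layer, cache, dout) {
  B <- cache$B; C <- cache$C; H <- cache$H; W <- cache$W
  H_out <- cache$H_out; W_out <- cache$W_out
  k <- layer$k; pad <- layer$pad; s <- layer$stride
  dmat <- matrix(aperm(dout, c(1, 3, 4, 2)), B * H_out * W_out, layer$out_ch)
  dW <- crossprod(cache$M, dmat)
  db <- colSums(dmat)
  dM <- dmat %*% t(layer$params$W)
  dXp <- array(0, c(B, C, H + 2L * pad, W + 2L * pad))
  for (j in seq_len(k)) {
    ws <- j + (seq_len(W_out) - 1L) * s
    for (i in seq_len(k)) {
      hs <- i + (seq_len(H_out) - 1L) * s
      q <- ((i - 1L) + (j - 1L) * k) * C + seq_len(C)
      blk <- aperm(array(dM[, q], c(B, H_out, W_out, C)), c(1, 4, 2, 3))
      dXp[, , hs, ws] <- dXp[, , hs, ws, drop = FALSE] + blk
    }
  }
  list(dx = dXp[, , pad + seq_len(H), pad + seq_len(W), drop = FALSE],
       grads = list(W = dW, b = db))
}

# ---- batch norm ------------------------------------------------------------

# channel axis is 2; flatten everything else into rows
bn_to_mat <- function(x) {
  nd <- length(dim(x))
  perm <- c(1, if (nd > 2) 3:nd else integer(0), 2)
  matrix(aperm(x, perm), ncol = dim(x)[2])
}

bn_from_mat <- function(m, dims) {
  nd <- length(dims)
  perm <- c(1, if (nd > 2) 3:nd else integer(0), 2)
  arr <- array(m, dims[perm])
  aperm(arr, order(perm))
}

bn_fwd <- function(layer, x, train) {
  dims <- dim(x)
  xm <- bn_to_mat(x)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  ivar <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, ivar, "*")
  outm <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
  list(out = bn_from_mat(outm, dims), layer = layer,
       cache = list(xhat = xhat, ivar = ivar, dims = dims))
}

bn_bwd <- function(layer, cache, dout) {
  dm <- bn_to_mat(dout)
  xhat <- cache$xhat
  m <- nrow(dm)
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, layer$params$gamma, "*")
  t1 <- sweep(dxhat * m, 2, colSums(dxhat), "-")
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat), "*")
  dxm <- sweep(t1 - t2, 2, cache$ivar / m, "*")
  list(dx = bn_from_mat(dxm, cache$dims), grads = list(gamma = dgamma, beta = dbeta))
}

# ---- layer dispatch --------------------------------------------------------

nn_layer_forward <- function(layer, x, train) {
  switch(layer$type,
    conv1d = c(conv1d_fwd(layer, x), list(layer = layer)),
    conv2d = c(conv2d_fwd(layer, x), list(layer = layer)),
    bn = bn_fwd(layer, x, train),
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    maxpool1d = {
      d <- dim(x); T_out <- d[3] %/% layer$size
      a <- x[, , 2 * seq_len(T_out) - 1L, drop = FALSE]
      b <- x[, , 2 * seq_len(T_out), drop = FALSE]
      takes_a <- a >= b
      list(out = ifelse(takes_a, a, b),
           cache = list(takes_a = takes_a, dims = d, T_out = T_out),
           layer = layer)
    },
    dropout = {
      if (train && layer$p > 0) {
        mask <- array((stats::runif(length(x)) >= layer$p) / (1 - layer$p), dim(x))
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = x, cache = list(mask = NULL), layer = layer)
      }
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1]), cache = list(dims = d), layer = layer)
    },
    avgpool = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2])
      list(out = matrix(rowMeans(xm), d[1], d[2]), cache = list(dims = d),
           layer = layer)
    },
    linear = {
      out <- sweep(x %*% layer$params$W, 2, layer$params$b, "+")
      list(out = out, cache = list(x = x), layer = layer)
    },
    resblock = resblock_fwd(layer, x, train),
    stop("unknown layer type: ", layer$type)
  )
}

nn_layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv1d = conv1d_bwd(layer, cache, dout),
    conv2d = conv2d_bwd(layer, cache, dout),
    bn = bn_bwd(layer, cache, dout),
    relu = list(dx = dout * cache$mask, grads = list()),
    maxpool1d = {
      d <- cache$dims; T_out <- cache$T_out
      dx <- array(0, d)
      dx[, , 2 * seq_len(T_out) - 1L] <- dout * cache$takes_a
      dx[, , 2 * seq_len(T_out)] <- dx[, , 2 * seq_len(T_out), drop = FALSE] +
        dout * !cache$takes_a
      list(dx = dx, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask, grads = list())
    },
    flatten = list(dx = array(dout, cache$dims), grads = list()),
    avgpool = {
      d <- cache$dims
      per <- d[3] * d[4]
      dx <- array(rep(as.numeric(dout) / per, times = per), d)
      list(dx = dx, grads = list())
    },
    linear = list(dx = dout %*% t(layer$params$W),
                  grads = list(W = crossprod(cache$x, dout), b = colSums(dout))),
    resblock = resblock_bwd(layer, cache, dout),
    stop("unknown layer type: ", layer$type)
  )
}

resblock_fwd <- function(layer, x, train) {
  f1 <- conv2d_fwd(layer$conv1, x)
  b1 <- bn_fwd(layer$bn1, f1$out, train); layer$bn1 <- b1$layer
  m1 <- b1$out > 0
  r1 <- b1$out * m1
  f2 <- conv2d_fwd(layer$conv2, r1)
  b2 <- bn_fwd(layer$bn2, f2$out, train); layer$bn2 <- b2$layer
  if (is.null(layer$shortcut)) {
    s <- x
    sc <- NULL
  } else {
    fs <- conv2d_fwd(layer$shortcut$conv, x)
    bs <- bn_fwd(layer$shortcut$bn, fs$out, train)
    layer$shortcut$bn <- bs$layer
    s <- bs$out
    sc <- list(conv = fs$cache, bn = bs$cache)
  }
  pre <- b2$out + s
  m_out <- pre > 0
  list(out = pre * m_out, layer = layer,
       cache = list(c1 = f1$cache, b1 = b1$cache, m1 = m1, c2 = f2$cache,
                    b2 = b2$cache, sc = sc, m_out = m_out))
}

resblock_bwd <- function(layer, cache, dout) {
  d <- dout * cache$m_out
  g_b2 <- bn_bwd(layer$bn2, cache$b2, d)
  g_c2 <- conv2d_bwd(layer$conv2, cache$c2, g_b2$dx)
  dr1 <- g_c2$dx * cache$m1
  g_b1 <- bn_bwd(layer$bn1, cache$b1, dr1)
  g_c1 <- conv2d_bwd(layer$conv1, cache$c1, g_b1$dx)
  dx <- g_c1$dx
  grads <- list(conv1 = g_c1$grads, bn1 = g_b1$grads,
                conv2 = g_c2$grads, bn2 = g_b2$grads)
  if (is.null(layer$shortcut)) {
    dx <- dx + d
    grads$shortcut <- list()
  } else {
    g_bs <- bn_bwd(layer$shortcut$bn, cache$sc$bn, d)
    g_cs <- conv2d_bwd(layer$shortcut$conv, cache$sc$conv, g_bs$dx)
    dx <- dx + g_cs$dx
    grads$shortcut <- list(conv = g_cs$grads, bn = g_bs$grads)
  }
  list(dx = dx, grads = grads)
}

# ---- model-level forward/backward and parameter plumbing -------------------

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- nn_layer_forward(layers[[i]], x, train)
    x <- step$out
    caches[[i]] <- step$cache
    layers[[i]] <- step$layer
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    step <- nn_layer_backward(layers[[i]], caches[[i]], dout)
    dout <- step$dx
    grads[[i]] <- step$grads
  }
  grads
}

nn_get_params <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "resblock") {
      list(conv1 = l$conv1$params, bn1 = l$bn1$params,
           conv2 = l$conv2$params, bn2 = l$bn2$params,
           shortcut = if (is.null(l$shortcut)) list() else
             list(conv = l$shortcut$conv$params, bn = l$shortcut$bn$params))
    } else l$params
  })
}

nn_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "resblock") {
      l$conv1$params <- params[[i]]$conv1
      l$bn1$params <- params[[i]]$bn1
      l$conv2$params <- params[[i]]$conv2
      l$bn2$params <- params[[i]]$bn2
      if (!is.null(l$shortcut)) {
        l$shortcut$conv$params <- params[[i]]$shortcut$conv
        l$shortcut$bn$params <- params[[i]]$shortcut$bn
      }
    } else {
      l$params <- params[[i]]
    }
    layers[[i]] <- l
  }
  layers
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, pvec, gvec, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gvec
  state$v <- beta2 * state$v + (1 - beta2) * gvec^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, pvec = pvec - lr * mhat / (sqrt(vhat) + eps))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss and gradient w.r.t. logits; y is 0-based
ce_loss <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, n, ncol(p))
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / n)
}
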