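# ---------------------------------------------------------------------------
# Minimal dense/convolutional/recurrent layer framework on BLAS.
#
# Every layer is a plain list: type, params (named numeric arrays), hyper,
# and optionally state (batch-norm running statistics). layerForward returns
# list(out, cache); layerBackward consumes the cache and the upstream
# gradient and returns list(din, grads) with grads matching params by name.
# Shapes: 1D signals (B, T, C); 2D images (B, H, W, C); dense (B, F).
# ---------------------------------------------------------------------------

nnInitMatrix <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  matrix(stats::rnorm(n_in * n_out, 0, scale), n_in, n_out)
}

layerConv1d <- function(name, k, cin, cout) {
  list(type = "conv1d", name = name,
       hyper = list(k = k, cin = cin, cout = cout, pad = (k - 1L) %/% 2L),
       params = list(W = nnInitMatrix(k * cin, cout), b = numeric(cout)))
}

layerConv2d <- function(name, k, cin, cout, stride = 1L) {
  list(type = "conv2d", name = name,
       hyper = list(k = k, cin = cin, cout = cout, stride = as.integer(stride),
                    pad = (k - 1L) %/% 2L),
       params = list(W = nnInitMatrix(k * k * cin, cout), b = numeric(cout)))
}

layerDense <- function(name, n_in, n_out) {
  list(type = "dense", name = name, hyper = list(n_in = n_in, n_out = n_out),
       params = list(W = nnInitMatrix(n_in, n_out), b = numeric(n_out)))
}

layerLSTM <- function(name, cin, units, return_seq = FALSE) {
  s <- 1 / sqrt(units)
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1          # forget-gate bias
  list(type = "lstm", name = name,
       hyper = list(cin = cin, units = units, return_seq = return_seq),
       params = list(
         Wx = matrix(stats::runif(cin * 4 * units, -s, s), cin, 4 * units),
         Wh = matrix(stats::runif(units * 4 * units, -s, s), units, 4 * units),
         b = b))
}

layerRelu <- function(name) list(type = "relu", name = name, params = list())
layerSigmoid <- function(name) list(type = "sigmoid", name = name, params = list())
layerFlatten <- function(name) list(type = "flatten", name = name, params = list())
layerMaxPool1d <- function(name) list(type = "maxpool1d", name = name, params = list())
layerMaxPool2d <- function(name) list(type = "maxpool2d", name = name, params = list())
layerGlobalAvgPool2d <- function(name)
  list(type = "gap2d", name = name, params = list())
layerDropout <- function(name, p) {
  list(type = "dropout", name = name, hyper = list(p = p), params = list())
}
layerBatchNorm <- function(name, c) {
  env <- new.env(parent = emptyenv())
  env$mean <- numeric(c)
  env$var <- rep(1, c)
  list(type = "batchnorm", name = name,
       hyper = list(c = c, eps = 1e-5, momentum = 0.9),
       params = list(gamma = rep(1, c), beta = numeric(c)),
       stateEnv = env)
}

# --- conv1d ---------------------------------------------------------------

im2col1d <- function(X, k, pad) {
  .Call(ctgnet_im2col1d, X, as.integer(k), as.integer(pad))
}

conv1dForward <- function(layer, X) {
  h <- layer$hyper
  d <- dim(X)
  M <- im2col1d(X, h$k, h$pad)
  Y <- M %*% layer$params$W
  Y <- Y + rep(layer$params$b, each = nrow(Y))
  dim(Y) <- c(d[1], d[2], h$cout)
  list(out = Y, cache = list(M = M, dims = d))
}

conv1dBackward <- function(layer, cache, dY) {
  h <- layer$hyper
  d <- cache$dims; B <- d[1]; T <- d[2]; C <- d[3]
  dYm <- dY; dim(dYm) <- c(B * T, h$cout)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, layer$params$W)
  dX <- .Call(ctgnet_col2im1d, dM, as.integer(h$k), as.integer(h$pad),
              as.integer(c(B, T, C)))
  list(din = dX, grads = list(W = dW, b = db))
}

# --- conv2d ---------------------------------------------------------------

im2col2d <- function(X, k, pad, stride) {
  d <- dim(X); B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  Xp <- array(0, c(B, H + 2 * pad, W + 2 * pad, C))
  Xp[, pad + seq_len(H), pad + seq_len(W), ] <- X
  M <- matrix(0, B * Ho * Wo, k * k * C)
  col <- 0L
  for (dc in seq_len(k)) for (dr in seq_len(k)) {
    rows <- seq.int(dr, by = stride, length.out = Ho)
    cols <- seq.int(dc, by = stride, length.out = Wo)
    sl <- Xp[, rows, cols, , drop = FALSE]
    dim(sl) <- c(B * Ho * Wo, C)
    M[, (col * C + 1L):((col + 1L) * C)] <- sl
    col <- col + 1L
  }
  list(M = M, Ho = Ho, Wo = Wo)
}

conv2dForward <- function(layer, X) {
  h <- layer$hyper
  d <- dim(X)
  ic <- im2col2d(X, h$k, h$pad, h$stride)
  Y <- ic$M %*% layer$params$W
  Y <- Y + rep(layer$params$b, each = nrow(Y))
  dim(Y) <- c(d[1], ic$Ho, ic$Wo, h$cout)
  list(out = Y, cache = list(M = ic$M, dims = d, Ho = ic$Ho, Wo = ic$Wo))
}

conv2dBackward <- function(layer, cache, dY) {
  h <- layer$hyper
  d <- cache$dims; B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- cache$Ho; Wo <- cache$Wo
  dYm <- dY; dim(dYm) <- c(B * Ho * Wo, h$cout)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, layer$params$W)
  dXp <- array(0, c(B, H + 2 * h$pad, W + 2 * h$pad, C))
  col <- 0L
  for (dc in seq_len(h$k)) for (dr in seq_len(h$k)) {
    rows <- seq.int(dr, by = h$stride, length.out = Ho)
    cols <- seq.int(dc, by = h$stride, length.out = Wo)
    blk <- dM[, (col * C + 1L):((col + 1L) * C), drop = FALSE]
    dim(blk) <- c(B, Ho, Wo, C)
    dXp[, rows, cols, ] <- dXp[, rows, cols, , drop = FALSE] + blk
    col <- col + 1L
  }
  dX <- dXp[, h$pad + seq_len(H), h$pad + seq_len(W), , drop = FALSE]
  list(din = dX, grads = list(W = dW, b = db))
}

# --- pooling --------------------------------------------------------------

maxpool1dForward <- function(X) {
  r <- .Call(ctgnet_maxpool1d_forward, X)
  list(out = r[[1]], cache = list(sel = r[[2]], dims = dim(X)))
}

maxpool1dBackward <- function(cache, dY) {
  .Call(ctgnet_maxpool1d_backward, dY, cache$sel, as.integer(cache$dims))
}

maxpool2dForward <- function(X) {
  d <- dim(X); Ho <- d[2] %/% 2L; Wo <- d[3] %/% 2L
  r1 <- 2 * seq_len(Ho) - 1L; r2 <- r1 + 1L
  c1 <- 2 * seq_len(Wo) - 1L; c2 <- c1 + 1L
  slices <- list(X[, r1, c1, , drop = FALSE], X[, r2, c1, , drop = FALSE],
                 X[, r1, c2, , drop = FALSE], X[, r2, c2, , drop = FALSE])
  out <- slices[[1]]; which_s <- array(1L, dim(out))
  for (s in 2:4) {
    upd <- slices[[s]] > out
    out[upd] <- slices[[s]][upd]
    which_s[upd] <- s
  }
  list(out = out, cache = list(dims = d, which_s = which_s, Ho = Ho, Wo = Wo))
}

maxpool2dBackward <- function(cache, dY) {
  d <- cache$dims; Ho <- cache$Ho; Wo <- cache$Wo
  r1 <- 2 * seq_len(Ho) - 1L; c1 <- 2 * seq_len(Wo) - 1L
  dX <- array(0, d)
  sel <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (s in 1:4) {
    m <- (cache$which_s == s) * dY
    dX[, r1 + sel[[s]][1], c1 + sel[[s]][2], ] <-
      dX[, r1 + sel[[s]][1], c1 + sel[[s]][2], , drop = FALSE] + m
  }
  dX
}

# --- lstm -----------------------------------------------------------------

sigm <- function(x) 1 / (1 + exp(-x))

lstmForward <- function(layer, X) {
  h <- layer$hyper; U <- h$units
  d <- dim(X); B <- d[1]; T <- d[2]
  # input projection for every timestep in one product; bias and the
  # sequential recurrence run in C
  Xm <- X; dim(Xm) <- c(B * T, h$cin)
  Zx <- Xm %*% layer$params$Wx
  r <- .Call(ctgnet_lstm_forward, Zx, layer$params$Wh, layer$params$b,
             as.integer(c(B, T, U)))
  Hs <- r[[1]]
  out <- if (h$return_seq) {
    O <- Hs; dim(O) <- c(B, T, U); O
  } else {
    Hs[(T - 1L) * B + seq_len(B), , drop = FALSE]
  }
  list(out = out, cache = list(Xm = Xm, Hs = Hs, Cs = r[[2]], TC = r[[3]],
                               G = r[[4]], dims = d))
}

lstmBackward <- function(layer, cache, dY) {
  h <- layer$hyper; U <- h$units
  d <- cache$dims; B <- d[1]; T <- d[2]
  if (h$return_seq) dim(dY) <- c(B * T, U)
  r <- .Call(ctgnet_lstm_backward, dY, cache$Hs, cache$Cs, cache$TC,
             cache$G, layer$params$Wh, as.integer(c(B, T, U)), h$return_seq)
  dZ <- r[[1]]
  dWx <- crossprod(cache$Xm, dZ)
  db <- colSums(dZ)
  dX <- tcrossprod(dZ, layer$params$Wx)
  dim(dX) <- c(B, T, h$cin)
  list(din = dX, grads = list(Wx = dWx, Wh = r[[2]], b = db))
}

# --- batch norm (per channel of (B, H, W, C)) -----------------------------

batchnormForward <- function(layer, X, training) {
  h <- layer$hyper
  d <- dim(X); C <- d[length(d)]
  Xm <- X; dim(Xm) <- c(prod(d) / C, C)
  if (training) {
    mu <- colMeans(Xm)
    va <- colMeans(sweep(Xm, 2, mu)^2)
    layer$stateEnv$mean <- h$momentum * layer$stateEnv$mean + (1 - h$momentum) * mu
    layer$stateEnv$var <- h$momentum * layer$stateEnv$var + (1 - h$momentum) * va
  } else {
    mu <- layer$stateEnv$mean; va <- layer$stateEnv$var
  }
  xhat <- sweep(sweep(Xm, 2, mu), 2, sqrt(va + h$eps), "/")
  Y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
  dim(Y) <- d
  list(out = Y, cache = list(xhat = xhat, mu = mu, va = va, dims = d))
}

batchnormBackward <- function(layer, cache, dY) {
  h <- layer$hyper
  d <- cache$dims; C <- d[length(d)]
  n <- prod(d) / C
  dYm <- dY; dim(dYm) <- c(n, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, layer$params$gamma, "*")
  inv_sd <- 1 / sqrt(cache$va + h$eps)
  dXm <- sweep(dxhat - matrix(colMeans(dxhat), n, C, byrow = TRUE) -
                 cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, C,
                                     byrow = TRUE),
               2, inv_sd, "*")
  dim(dXm) <- d
  list(din = dXm, grads = list(gamma = dgamma, beta = dbeta))
}

# --- generic dispatch -----------------------------------------------------

layerForward <- function(layer, X, training = FALSE) {
  switch(layer$type,
    conv1d = conv1dForward(layer, X),
    conv2d = conv2dForward(layer, X),
    dense = {
      Y <- X %*% layer$params$W
      Y <- Y + rep(layer$params$b, each = nrow(Y))
      list(out = Y, cache = list(X = X))
    },
    lstm = lstmForward(layer, X),
    relu = list(out = pmax(X, 0), cache = list(mask = X > 0)),
    sigmoid = { s <- sigm(X); list(out = s, cache = list(s = s)) },
    flatten = {
      d <- dim(X)
      Y <- X; dim(Y) <- c(d[1], prod(d[-1]))
      list(out = Y, cache = list(dims = d))
    },
    maxpool1d = maxpool1dForward(X),
    maxpool2d = maxpool2dForward(X),
    gap2d = {
      d <- dim(X)
      Xm <- X; dim(Xm) <- c(d[1], d[2] * d[3], d[4])
      list(out = apply(Xm, c(1, 3), mean), cache = list(dims = d))
    },
    dropout = {
      if (training && layer$hyper$p > 0) {
        keep <- (stats::runif(length(X)) >= layer$hyper$p) /
          (1 - layer$hyper$p)
        dim(keep) <- dim(X)
        list(out = X * keep, cache = list(keep = keep))
      } else list(out = X, cache = list(keep = NULL))
    },
    batchnorm = batchnormForward(layer, X, training),
    stop("unknown layer type ", layer$type))
}

layerBackward <- function(layer, cache, dY) {
  switch(layer$type,
    conv1d = conv1dBackward(layer, cache, dY),
    conv2d = conv2dBackward(layer, cache, dY),
    dense = list(din = tcrossprod(dY, layer$params$W),
                 grads = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    lstm = lstmBackward(layer, cache, dY),
    relu = list(din = dY * cache$mask, grads = list()),
    sigmoid = list(din = dY * cache$s * (1 - cache$s), grads = list()),
    flatten = { dX <- dY; dim(dX) <- cache$dims
                list(din = dX, grads = list()) },
    maxpool1d = list(din = maxpool1dBackward(cache, dY), grads = list()),
    maxpool2d = list(din = maxpool2dBackward(cache, dY), grads = list()),
    gap2d = {
      d <- cache$dims
      per <- dY / (d[2] * d[3])                     # (B, C)
      dX <- aperm(array(per, c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
      list(din = dX, grads = list())
    },
    dropout = list(din = if (is.null(cache$keep)) dY else dY * cache$keep,
                   grads = list()),
    batchnorm = batchnormBackward(layer, cache, dY),
    stop("unknown layer type ", layer$type))
}

chainForward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layerForward(layers[[i]], X, training)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

chainBackward <- function(layers, caches, dY) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    r <- layerBackward(layers[[i]], caches[[i]], dY)
    dY <- r$din
    if (length(r$grads)) grads[[layers[[i]]$name]] <- r$grads
  }
  list(din = dY, grads = grads)
}

# --- Adam -----------------------------------------------------------------

adamInit <- function(params_by_layer) {
  lapply(params_by_layer, function(ps)
    lapply(ps, function(p) list(m = p * 0, v = p * 0)))
}

adamStep <- function(params_by_layer, grads_by_layer, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ln in names(grads_by_layer)) {
    for (pn in names(grads_by_layer[[ln]])) {
      g <- grads_by_layer[[ln]][[pn]]
      s <- state[[ln]][[pn]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mh <- s$m / (1 - beta1^t)
      vh <- s$v / (1 - beta2^t)
      params_by_layer[[ln]][[pn]] <-
        params_by_layer[[ln]][[pn]] - lr * mh / (sqrt(vh) + eps)
      state[[ln]][[pn]] <- s
    }
  }
  list(params = params_by_layer, state = state)
}

# --- weighted binary cross-entropy ----------------------------------------

#' Weighted binary cross-entropy loss
#'
#' Mean of \code{-(w * y * log(p) + (1 - y) * log(1 - p))}: positive-class
#' errors are penalised \code{pos_weight} times more, the inverse-class-
#' frequency weighting used for the severely imbalanced outcome.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y 0/1 labels.
#' @param pos_weight positive-class weight (1 = unweighted).
#' @return scalar loss.
#' @export
weightedBCE <- function(p, y, pos_weight = 1) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(pos_weight * y * log(p) + (1 - y) * log(1 - p))
}

# gradient of the summed-then-averaged loss w.r.t. the pre-sigmoid logit
bceLogitGrad <- function(p, y, pos_weight = 1) {
  ((1 - y) * p - pos_weight * y * (1 - p)) / length(y)
}
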