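# Analytic backward passes checked against central finite differences on a
# scalar readout loss sum(out * R).

numGradCheck <- function(layer, X, R, eps = 1e-6, tol = 1e-4,
                         training = FALSE) {
  fw <- ctgnet:::layerForward(layer, X, training)
  bw <- ctgnet:::layerBackward(layer, fw$cache, R)
  readout <- function(l, x) sum(ctgnet:::layerForward(l, x, training)$out * R)
  for (pn in names(layer$params)) {
    g <- bw$grads[[pn]]
    for (k in seq_along(g)) {
      l2 <- layer
      l2$params[[pn]][k] <- l2$params[[pn]][k] + eps
      up <- readout(l2, X)
      l2$params[[pn]][k] <- l2$params[[pn]][k] - 2 * eps
      dn <- readout(l2, X)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - g[k]) / max(abs(num), abs(g[k]), 1), tol)
    }
  }
  for (k in seq_along(X)) {
    X2 <- X
    X2[k] <- X2[k] + eps
    up <- readout(layer, X2)
    X2[k] <- X2[k] - 2 * eps
    dn <- readout(layer, X2)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - bw$din[k]) / max(abs(num), abs(bw$din[k]), 1), tol)
  }
}

test_that("conv1d gradients match finite differences", {
  set.seed(40)
  l <- ctgnet:::layerConv1d("c", 3, 2, 4)
  numGradCheck(l, array(rnorm(3 * 6 * 2), c(3, 6, 2)),
               array(rnorm(3 * 6 * 4), c(3, 6, 4)))
})

test_that("conv2d gradients match finite differences, including stride 2", {
  set.seed(41)
  l <- ctgnet:::layerConv2d("c", 3, 2, 3)
  numGradCheck(l, array(rnorm(2 * 6 * 6 * 2), c(2, 6, 6, 2)),
               array(rnorm(2 * 6 * 6 * 3), c(2, 6, 6, 3)))
  l2 <- ctgnet:::layerConv2d("c2", 3, 1, 2, stride = 2L)
  numGradCheck(l2, array(rnorm(2 * 8 * 8), c(2, 8, 8, 1)),
               array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2)))
})

test_that("LSTM gradients match finite differences in both output modes", {
  set.seed(42)
  l <- ctgnet:::layerLSTM("l", 2, 3, return_seq = TRUE)
  numGradCheck(l, array(rnorm(2 * 5 * 2), c(2, 5, 2)),
               array(rnorm(2 * 5 * 3), c(2, 5, 3)))
  l2 <- ctgnet:::layerLSTM("l2", 2, 3, return_seq = FALSE)
  numGradCheck(l2, array(rnorm(2 * 5 * 2), c(2, 5, 2)),
               matrix(rnorm(2 * 3), 2, 3))
})

test_that("dense, pooling and batch-norm gradients match finite differences", {
  set.seed(43)
  numGradCheck(ctgnet:::layerDense("d", 4, 3), matrix(rnorm(12), 3, 4),
               matrix(rnorm(9), 3, 3))
  X <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
  numGradCheck(ctgnet:::layerMaxPool1d("p"), X,
               array(rnorm(3 * 3 * 2), c(3, 3, 2)))
  X2 <- array(rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
  numGradCheck(ctgnet:::layerMaxPool2d("p2"), X2,
               array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2)))
  # batch norm in training mode (batch statistics in the graph)
  bn <- ctgnet:::layerBatchNorm("bn", 2)
  numGradCheck(bn, X2, array(rnorm(length(X2)), dim(X2)), training = TRUE,
               tol = 5e-4)
})

test_that("residual block composite backward matches finite differences", {
  set.seed(44)
  blk <- ctgnet:::makeResBlock("rb", 3, 2, 3, dropout = 0)
  X <- array(rnorm(2 * 6 * 6 * 2), c(2, 6, 6, 2))
  R <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  fw <- ctgnet:::moduleForward(list(blk), X, training = TRUE)
  bw <- ctgnet:::moduleBackward(list(blk), fw$caches, R)
  readout <- function(b, x)
    sum(ctgnet:::moduleForward(list(b), x, training = TRUE)$out * R)
  eps <- 1e-6
  # spot-check the main conv and the projection weights
  for (path in c("main", "skip")) {
    lname <- blk[[path]][[1]]$name
    g <- bw$grads[[lname]]$W
    for (k in sample(length(g), 6)) {
      b2 <- blk
      b2[[path]][[1]]$params$W[k] <- b2[[path]][[1]]$params$W[k] + eps
      up <- readout(b2, X)
      b2[[path]][[1]]$params$W[k] <- b2[[path]][[1]]$params$W[k] - 2 * eps
      dn <- readout(b2, X)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - g[k]) / max(abs(num), abs(g[k]), 1), 5e-4)
    }
  }
})

test_that("weighted BCE reduces to unweighted at the zero-residual limit", {
  p <- c(1 - 1e-9, 1e-9, 1 - 1e-9)
  y <- c(1, 0, 1)
  expect_equal(weightedBCE(p, y, 14), weightedBCE(p, y, 1), tolerance = 1e-6)
  # and the weight scales only the positive terms
  p2 <- c(0.6, 0.4)
  y2 <- c(1, 0)
  expect_equal(weightedBCE(p2, y2, 3),
               mean(c(-3 * log(0.6), -log(0.6))))
})

test_that("the loss gradient at the logit matches finite differences", {
  set.seed(45)
  logit <- rnorm(6)
  y <- rbinom(6, 1, 0.5)
  w <- 5
  p <- 1 / (1 + exp(-logit))
  g <- ctgnet:::bceLogitGrad(p, y, w)
  eps <- 1e-6
  for (k in 1:6) {
    l2 <- logit; l2[k] <- l2[k] + eps
    up <- weightedBCE(1 / (1 + exp(-l2)), y, w)
    l2[k] <- l2[k] - 2 * eps
    dn <- weightedBCE(1 / (1 + exp(-l2)), y, w)
    expect_equal(g[k], (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})
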