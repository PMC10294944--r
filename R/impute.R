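#' Gap statistics of a validity mask
#'
#' Summarises the missingness of a trace before imputation: loss fraction,
#' number of gaps (maximal runs of invalid samples), length of the longest
#' gap and its location (start of the longest gap as a fraction of the
#' trace length; ties broken by the earliest gap).
#'
#' @param mask logical vector or an object with a validity mask
#'   (\code{TRUE} = valid).
#' @return A list of class \code{"GapStats"} with \code{loss_fraction},
#'   \code{n_gaps}, \code{longest_gap}, \code{longest_gap_location}.
#' @examples
#' gapStats(c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
#' @export
gapStats <- function(mask) {
  if (!is.logical(mask)) mask <- validMask(mask)
  n <- length(mask)
  if (n == 0L) stop("empty mask")
  r <- rle(mask)
  gap_lens <- r$lengths[!r$values]
  if (length(gap_lens) == 0L) {
    out <- list(loss_fraction = 0, n_gaps = 0L, longest_gap = 0L,
                longest_gap_location = 0)
  } else {
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    gap_starts <- starts[!r$values]
    k <- which.max(gap_lens)          # earliest on ties
    out <- list(loss_fraction = mean(!mask),
                n_gaps = length(gap_lens),
                longest_gap = as.integer(gap_lens[k]),
                longest_gap_location = (gap_starts[k] - 1L) / n)
  }
  class(out) <- "GapStats"
  out
}

segToFill <- function(segment) {
  stopifnot(is(segment, "FHRSegment"))
  list(x = segment@values, m = segment@validMask)
}

fillReturn <- function(segment, filled) {
  segment@values <- filled
  segment@validMask <- rep(TRUE, length(filled))
  segment
}

#' Linear gap imputation
#'
#' Interior gaps are linearly interpolated between the flanking valid
#' samples; leading and trailing gaps take the nearest valid value.
#' Observed samples are returned unchanged.
#'
#' @param segment an \linkS4class{FHRSegment} with at least one valid
#'   sample.
#' @return The segment with all samples valid.
#' @export
imputeLinear <- function(segment) {
  sf <- segToFill(segment)
  if (!any(sf$m)) stop("no valid samples to interpolate from")
  x <- sf$x
  x[!sf$m] <- NA
  filled <- stats::approx(which(sf$m), x[sf$m], xout = seq_along(x),
                          method = "linear", rule = 2)$y
  filled[sf$m] <- sf$x[sf$m]
  fillReturn(segment, filled)
}

#' Autoregressive imputation configuration
#'
#' @param max_order maximum AR order (>= 1).
#' @param order_criterion \code{"AIC"} (order chosen by AIC up to
#'   \code{max_order}) or \code{"fixed"} (exactly \code{max_order}).
#' @param blend \code{"forward_backward"} (gaps filled by the conditional
#'   mean of the fitted AR model, which combines the forward and backward
#'   forecasts with the model-implied distance weights) or
#'   \code{"forward"} (one-sided recursion only).
#' @return A list of class \code{"ARConfig"}.
#' @export
arConfig <- function(max_order = 10, order_criterion = c("AIC", "fixed"),
                     blend = c("forward_backward", "forward")) {
  if (max_order < 1) stop("max_order must be >= 1")
  structure(list(max_order = as.integer(max_order),
                 order_criterion = match.arg(order_criterion),
                 blend = match.arg(blend)),
            class = "ARConfig")
}

arForecast <- function(history, coefs, mean_x, h) {
  p <- length(coefs)
  hist_c <- history - mean_x
  out <- numeric(h)
  ext <- c(hist_c, out)
  n0 <- length(hist_c)
  for (i in seq_len(h)) {
    ext[n0 + i] <- sum(coefs * ext[n0 + i - seq_len(p)])
  }
  ext[n0 + seq_len(h)] + mean_x
}

#' Autoregressive gap imputation
#'
#' Fits an AR model (Yule-Walker equations, order selected by AIC up to
#' \code{max_order}) to the longest observed run, mean-removed, then fills
#' the gaps with the model forecast. The default two-sided mode uses the
#' fitted model's conditional mean, which blends the forward forecast
#' (from the samples before a gap) with the backward forecast (from the
#' samples after it) at the model-implied distance weights; leading and
#' trailing runs decay towards the mean like one-sided forecasts. Falls
#' back to linear interpolation, with a warning, when the observed data
#' cannot support the fit.
#'
#' @param segment an \linkS4class{FHRSegment}.
#' @param cfg an \code{\link{arConfig}}.
#' @return The segment with all samples valid; observed samples unchanged.
#' @export
imputeAR <- function(segment, cfg = arConfig()) {
  sf <- segToFill(segment)
  m <- sf$m; x <- sf$x
  if (!any(m)) stop("no valid samples to impute from")
  r <- rle(m)
  run_lens <- r$lengths[r$values]
  longest_run <- if (length(run_lens)) max(run_lens) else 0L
  if (longest_run <= cfg$max_order + 1L || stats::sd(x[m]) == 0) {
    if (stats::sd(x[m]) > 0)
      warning("insufficient observed data for AR fit; falling back to linear")
    return(imputeLinear(segment))
  }

  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  run_idx <- which(r$values)[which.max(run_lens)]
  run <- x[starts[run_idx]:(starts[run_idx] + max(run_lens) - 1L)]

  mean_x <- mean(x[m])
  ord_max <- min(cfg$max_order, length(run) - 1L)
  fit <- stats::ar(run, aic = (cfg$order_criterion == "AIC"),
                   order.max = ord_max, method = "yule-walker",
                   demean = TRUE)
  coefs <- fit$ar
  if (length(coefs) == 0L) {           # AIC chose white noise: mean fill
    filled <- x; filled[!m] <- mean_x
    return(fillReturn(segment, filled))
  }
  p <- length(coefs)

  filled <- x
  gap_starts <- starts[!r$values]
  gap_lens <- r$lengths[!r$values]
  n <- length(x)
  if (cfg$blend == "forward_backward") {
    filled <- arConditionalFill(x, m, coefs, mean_x)
  } else {
    for (g in seq_along(gap_starts)) {
      a <- gap_starts[g]; len <- gap_lens[g]; b <- a + len - 1L
      fwd_hist <- if (a > 1L) x[max(1L, a - 5L * p):(a - 1L)] else numeric(0)
      bwd_hist <- if (b < n) rev(x[(b + 1L):min(n, b + 5L * p)]) else numeric(0)
      fill <- if (length(fwd_hist) >= p) {
        arForecast(fwd_hist, coefs, mean_x, len)
      } else if (length(bwd_hist) >= p) {
        rev(arForecast(bwd_hist, coefs, mean_x, len))
      } else rep(mean_x, len)
      filled[a:b] <- fill
    }
  }
  filled[m] <- x[m]
  if (!all(is.finite(filled))) stop("AR imputation produced non-finite values")
  fillReturn(segment, filled)
}

# Conditional mean of the missing samples under the fitted AR model: the
# AR(p) precision matrix is banded with entries from the autocorrelation
# of (1, -phi); solving its normal equations over the missing positions
# blends the forward and backward information with the model-implied
# distance weights (for AR(1) this reduces to the classic two-sided
# bridge). Rows within p of the series boundary use the clipped band, and
# leading/trailing runs therefore decay towards the mean as one-sided
# forecasts do.
arConditionalFill <- function(x, m, coefs, mean_x) {
  if (all(m)) return(x)
  p <- length(coefs)
  n <- length(x)
  theta <- c(1, -coefs)
  rq <- vapply(0:p, function(l)
    sum(theta[seq_len(p + 1 - l)] * theta[(1 + l):(p + 1)]), 0)
  mis <- which(!m)
  xc <- x - mean_x
  xc[mis] <- 0
  A <- matrix(0, length(mis), length(mis))
  b <- numeric(length(mis))
  pos_of <- integer(n)
  pos_of[mis] <- seq_along(mis)
  for (k in seq_along(mis)) {
    i <- mis[k]
    js <- max(1L, i - p):min(n, i + p)
    qs <- rq[abs(js - i) + 1L]
    miss_j <- !m[js]
    A[k, pos_of[js[miss_j]]] <- qs[miss_j]
    b[k] <- -sum(qs[!miss_j] * xc[js[!miss_j]])
  }
  sol <- solve(A, b)
  out <- x
  out[mis] <- mean_x + sol
  out
}

#' Gaussian-process gap imputation (posterior mean)
#'
#' Fills gaps with the posterior mean of a Gaussian process with a squared
#' exponential kernel conditioned on the observed samples; deterministic
#' given the kernel parameters. Provided for parity with the linear and AR
#' strategies; AR is the pipeline default.
#'
#' @param segment an \linkS4class{FHRSegment}.
#' @param length_scale kernel length scale in samples.
#' @param signal_var kernel signal variance.
#' @param noise_var observation noise variance.
#' @param max_obs subsample cap on conditioning points (nearest are kept
#'   exact via sorting; caps the cubic solve).
#' @return The segment with all samples valid; observed samples unchanged.
#' @export
imputeGP <- function(segment, length_scale = 20, signal_var = 25,
                     noise_var = 1, max_obs = 400) {
  sf <- segToFill(segment)
  m <- sf$m; x <- sf$x
  if (!any(m)) stop("no valid samples to impute from")
  if (all(m)) return(fillReturn(segment, x))
  obs <- which(m)
  if (length(obs) > max_obs)
    obs <- obs[unique(round(seq(1, length(obs), length.out = max_obs)))]
  mis <- which(!m)
  mu <- mean(x[obs])
  k <- function(a, b) signal_var * exp(-0.5 * outer(a, b, "-")^2 / length_scale^2)
  K <- k(obs, obs) + diag(noise_var, length(obs))
  alpha <- solve(K, x[obs] - mu)
  fill <- as.vector(k(mis, obs) %*% alpha) + mu
  filled <- x
  filled[mis] <- fill
  fillReturn(segment, filled)
}

#' Impute a segment with the configured strategy
#'
#' @param segment an \linkS4class{FHRSegment}.
#' @param method one of \code{"ar"} (default, the pipeline's selected
#'   strategy), \code{"linear"}, \code{"gp"}.
#' @param ... passed to the strategy.
#' @return Fully valid segment.
#' @export
imputeSegment <- function(segment, method = c("ar", "linear", "gp"), ...) {
  method <- match.arg(method)
  switch(method,
         ar = imputeAR(segment, ...),
         linear = imputeLinear(segment),
         gp = imputeGP(segment, ...))
}
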