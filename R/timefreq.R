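#' Short-time Fourier transform parameters
#'
#' @param window_length window length L in samples; the sweep set used for
#'   model comparison is 32, 64, 128, 256 (64 is the best-performing
#'   default).
#' @param overlap overlap between consecutive windows, samples; defaults
#'   to L/2.
#' @param window_function taper; only \code{"hann"} is provided.
#' @param log_eps positive constant added before taking logs.
#' @return List of class \code{"STFTParams"}.
#' @export
stftParams <- function(window_length = 64, overlap = window_length / 2,
                       window_function = "hann", log_eps = 1e-10) {
  if (overlap >= window_length) stop("overlap must be smaller than window_length")
  if (log_eps <= 0) stop("log_eps must be positive")
  if (!identical(window_function, "hann"))
    stop("only the 'hann' window is supported")
  structure(list(window_length = as.integer(window_length),
                 overlap = as.integer(overlap),
                 window_function = window_function, log_eps = log_eps),
            class = "STFTParams")
}

#' Continuous wavelet transform parameters
#'
#' @param wavelet one of \code{"mexh"} (Mexican hat, the best-performing
#'   default), \code{"morl"} (Morlet), \code{"shan"} (Shannon, complex,
#'   bandwidth 1.5 / centre 1.0), \code{"gaus8"} (8th-order Gaussian
#'   derivative).
#' @param scales strictly increasing positive scale grid; defaults to 128
#'   logarithmically spaced scales spanning pseudo-periods 2-256 s at 1 Hz
#'   (covering the baseline-to-variability band).
#' @return List of class \code{"CWTParams"}.
#' @export
cwtParams <- function(wavelet = c("mexh", "morl", "shan", "gaus8"),
                      scales = NULL) {
  if (length(wavelet) == 1L && !wavelet %in% c("mexh", "morl", "shan", "gaus8"))
    stop("unknown wavelet '", wavelet,
         "'; supported: mexh, morl, shan, gaus8")
  wavelet <- match.arg(wavelet)
  if (is.null(scales)) {
    fc <- centreFrequency(wavelet)
    scales <- exp(seq(log(2 * fc), log(256 * fc), length.out = 128))
  }
  if (any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing and positive")
  structure(list(wavelet = wavelet, scales = scales), class = "CWTParams")
}

hannWindow <- function(L) 0.5 * (1 - cos(2 * pi * seq.int(0, L - 1) / (L - 1)))

#' Raw STFT power frames
#'
#' Frames the signal at stride \code{L - overlap}, applies the Hann taper
#' and returns the magnitude-squared DFT over the non-negative frequency
#' bins, before any log/resize/scaling.
#'
#' @param x fully imputed numeric signal.
#' @param params an \code{\link{stftParams}}.
#' @return \code{(L/2 + 1) x n_frames} matrix of power values; attribute
#'   \code{freq} gives the bin frequencies in cycles/sample.
#' @export
stftFrames <- function(x, params) {
  L <- params$window_length
  hop <- L - params$overlap
  n <- length(x)
  if (n < L) stop("signal shorter than the analysis window")
  n_frames <- (n - L) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) x[(s + 1L):(s + L)], numeric(L))
  frames <- frames * hannWindow(L)
  spec <- stats::mvfft(frames)
  n_bins <- L %/% 2L + 1L
  pow <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  attr(pow, "freq") <- (seq_len(n_bins) - 1L) / L
  pow
}

minMaxImage <- function(m) {
  lo <- min(m); hi <- max(m)
  # guard against numerically constant images (e.g. all-zero input), where
  # interpolation ripple would otherwise be stretched across [0, 1]
  if (hi - lo <= 1e-9 * max(abs(lo), abs(hi), 1))
    return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

resizeBilinear <- function(m, w = 128L, h = 128L) {
  out <- EBImage::resize(EBImage::Image(m), w = w, h = h, filter = "bilinear")
  matrix(EBImage::imageData(out), w, h)
}

#' Spectrogram image of a 1 Hz FHR segment
#'
#' Log power of the short-time Fourier transform over non-negative
#' frequencies, bilinearly resized to 128 x 128 and min-max scaled to
#' [0, 1] per image. An all-constant signal yields a uniform image.
#'
#' @param x fully imputed numeric signal (1200 samples for a 20-min
#'   segment at 1 Hz) or an imputed \linkS4class{FHRSegment} at 1 Hz.
#' @param params an \code{\link{stftParams}}.
#' @return A \linkS4class{TFImage} (rows = frequency, columns = time).
#' @export
spectrogram <- function(x, params = stftParams()) {
  if (is(x, "FHRSegment")) {
    if (!all(x@validMask)) stop("segment must be imputed first")
    x <- x@values
  }
  pow <- stftFrames(x, params)
  img <- minMaxImage(resizeBilinear(log(pow + params$log_eps)))
  new("TFImage", pixels = img, kind = "spectrogram", params = unclass(params))
}

waveletFunction <- function(wavelet) {
  switch(wavelet,
    mexh = list(
      psi = function(t) (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2),
      support = 8, complex = FALSE, fc = sqrt(2) / (2 * pi)),
    morl = list(
      psi = function(t) exp(-t^2 / 2) * cos(5 * t),
      support = 8, complex = FALSE, fc = 5 / (2 * pi)),
    shan = list(                      # shan1.5-1.0
      psi = function(t) {
        B <- 1.5; C <- 1
        sqrt(B) * ifelse(t == 0, 1, sin(pi * B * t) / (pi * B * t)) *
          exp(2i * pi * C * t)
      },
      support = 20, complex = TRUE, fc = 1),
    gaus8 = list(
      psi = function(t) {
        h8 <- 256 * t^8 - 3584 * t^6 + 13440 * t^4 - 13440 * t^2 + 1680
        psi <- h8 * exp(-t^2)
        psi / sqrt(sum(psi^2) * (t[2] - t[1]))   # unit energy on this grid
      },
      support = 5, complex = FALSE, fc = 4 / (2 * pi)),
    stop("unknown wavelet '", wavelet,
         "'; supported: mexh, morl, shan, gaus8"))
}

#' Centre frequency of a mother wavelet
#'
#' The dominant frequency of the mother wavelet (the peak of its Fourier
#' magnitude; for the band-limited Shannon wavelet, the centre of its
#' passband), in cycles per unit time at scale 1. The pseudo-frequency at
#' scale \code{a} and sampling step \code{dt} is \code{fc / (a * dt)}.
#'
#' @param wavelet wavelet name.
#' @return centre frequency in cycles/sample.
#' @export
centreFrequency <- function(wavelet) {
  waveletFunction(wavelet)$fc
}

convCentred <- function(x, k) {
  # full convolution, centre-aligned with x (k has odd length)
  full <- stats::convolve(x, rev(k), type = "open")
  off <- (length(k) - 1L) / 2L
  full[(off + 1L):(off + length(x))]
}

#' Raw continuous wavelet coefficients
#'
#' \code{|W(a, b)|} over the scale grid and every sample translation,
#' computed by direct convolution of the signal with the sampled, scaled
#' mother wavelet \code{psi(t / a) / sqrt(a)}.
#'
#' @param x fully imputed numeric signal.
#' @param params a \code{\link{cwtParams}}.
#' @return \code{length(scales) x length(x)} matrix of absolute
#'   coefficients; attribute \code{scales} carries the grid.
#' @export
cwtCoefficients <- function(x, params) {
  wf <- waveletFunction(params$wavelet)
  n <- length(x)
  out <- matrix(0, length(params$scales), n)
  for (i in seq_along(params$scales)) {
    a <- params$scales[i]
    half <- ceiling(wf$support * a)
    t <- seq.int(-half, half)
    k <- wf$psi(t / a) / sqrt(a)
    if (wf$complex) {
      re <- convCentred(x, Re(k))
      im <- convCentred(x, Im(k))
      out[i, ] <- sqrt(re^2 + im^2)
    } else {
      out[i, ] <- abs(convCentred(x, as.numeric(k)))
    }
  }
  attr(out, "scales") <- params$scales
  out
}

#' Scalogram image of a 1 Hz FHR segment
#'
#' Absolute continuous wavelet coefficients over the scale grid, resized
#' to 128 x 128 and min-max scaled to [0, 1].
#'
#' @param x fully imputed numeric signal or imputed
#'   \linkS4class{FHRSegment} at 1 Hz.
#' @param params a \code{\link{cwtParams}}.
#' @return A \linkS4class{TFImage} (rows = scale, columns = time).
#' @export
scalogram <- function(x, params = cwtParams()) {
  if (is(x, "FHRSegment")) {
    if (!all(x@validMask)) stop("segment must be imputed first")
    x <- x@values
  }
  co <- cwtCoefficients(x, params)
  img <- minMaxImage(resizeBilinear(co))
  new("TFImage", pixels = img, kind = "scalogram", params = unclass(params))
}

#' Stack a TFImage into the three-channel tensor the 2D networks expect
#'
#' @param image a \linkS4class{TFImage}.
#' @return 128 x 128 x 3 array (the plane replicated).
#' @export
imageTensor <- function(image) {
  stopifnot(is(image, "TFImage"))
  array(rep(image@pixels, 3L), dim = c(128L, 128L, 3L))
}
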