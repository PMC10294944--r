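test_that("frame counts and bin counts follow the STFT arithmetic", {
  x <- sin(2 * pi * 0.1 * (0:1199))
  pow <- stftFrames(x, stftParams(window_length = 64, overlap = 32))
  # floor((1200 - 64)/32) + 1 frames, L/2 + 1 non-negative bins
  expect_equal(dim(pow), c(33, 36))
  for (L in c(32, 128, 256)) {
    p <- stftFrames(x, stftParams(window_length = L))
    expect_equal(dim(p), c(L / 2 + 1, (1200 - L) %/% (L / 2) + 1))
  }
  expect_error(stftFrames(x[1:50], stftParams(window_length = 64)), "shorter")
  expect_error(stftParams(window_length = 64, overlap = 64), "overlap")
})

test_that("pure sinusoids peak at the nearest DFT bin in every frame", {
  params <- stftParams(window_length = 64, overlap = 32)
  for (f in c(0.05, 0.125, 0.3)) {
    x <- sin(2 * pi * f * (0:1199))
    pow <- stftFrames(x, params)
    freqs <- attr(pow, "freq")
    expected_bin <- which.min(abs(freqs - f))
    peaks <- apply(pow, 2, which.max)
    expect_true(all(peaks == expected_bin))
  }
})

test_that("frame powers agree with an independent direct DFT oracle", {
  set.seed(8)
  x <- rnorm(1200)
  params <- stftParams(window_length = 64, overlap = 32)
  pow <- stftFrames(x, params)
  # oracle: explicit DFT sum of the first windowed frame
  L <- 64
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  frame <- x[1:L] * w
  for (k in c(1, 5, 20, 33)) {
    Xk <- sum(frame * exp(-2i * pi * (k - 1) * (0:(L - 1)) / L))
    expect_equal(pow[k, 1], Mod(Xk)^2, tolerance = 1e-9)
  }
  # Parseval-style energy ordering: doubled amplitude -> 4x frame power
  pow2 <- stftFrames(2 * x, params)
  expect_equal(pow2, 4 * pow, tolerance = 1e-12)
})

test_that("spectrogram frames match signal::specgram on the shared bins", {
  skip_if_not_installed("signal")
  set.seed(9)
  x <- rnorm(500)
  pow <- stftFrames(x, stftParams(window_length = 64, overlap = 32))
  ref <- signal::specgram(x, n = 64, Fs = 1,
                          window = signal::hanning(64), overlap = 32)
  # specgram drops the Nyquist bin; compare the first 32 rows
  expect_equal(unname(pow[1:32, ]), unname(Mod(ref$S)^2), tolerance = 1e-6)
})

test_that("spectrogram and scalogram images satisfy the TFImage contract", {
  set.seed(10)
  x <- 140 + 5 * sin(2 * pi * (0:1199) / 60) + rnorm(1200)
  for (img in list(spectrogram(x), scalogram(x, cwtParams("mexh")))) {
    px <- imagePixels(img)
    expect_equal(dim(px), c(128L, 128L))
    expect_true(all(is.finite(px)))
    expect_gte(min(px), 0)
    expect_lte(max(px), 1)
  }
  # zero (constant) input collapses to a uniform image under the guard
  expect_true(all(imagePixels(spectrogram(rep(0, 1200))) == 0))
  expect_true(all(imagePixels(scalogram(rep(0, 1200))) == 0))
  # determinism
  expect_identical(imagePixels(scalogram(x)), imagePixels(scalogram(x)))
})

test_that("every window length and wavelet yields a valid image on a simulated segment", {
  rec <- simulateRecord(cleanSimParams(seed = 31), 0)
  seg <- imputeLinear(extractSegment(removeArtifacts(rec), 0, 20))
  x1 <- fhrValues(downsampleFHR(seg, 1))
  for (L in c(32, 64, 128, 256)) {
    img <- spectrogram(x1, stftParams(window_length = L))
    expect_s4_class(img, "TFImage")
  }
  for (wv in c("mexh", "morl", "shan", "gaus8")) {
    img <- scalogram(x1, cwtParams(wv))
    expect_s4_class(img, "TFImage")
    expect_true(validObject(img))
  }
})

test_that("centre frequencies match the spectral peak of the sampled wavelets", {
  # independent check: zero-padded FFT of the finely sampled mother wavelet
  for (wv in c("mexh", "morl", "gaus8")) {
    wf <- ctgnet:::waveletFunction(wv)
    dt <- 0.01
    t <- seq(-wf$support, wf$support, by = dt)
    psi <- as.numeric(wf$psi(t))
    n_pad <- 2^16
    spec <- Mod(stats::fft(c(psi, numeric(n_pad - length(psi)))))
    freqs <- (seq_len(n_pad %/% 2) - 1) / (n_pad * dt)
    f_peak <- freqs[which.max(spec[seq_len(n_pad %/% 2)])]
    expect_equal(centreFrequency(wv), f_peak, tolerance = 0.01)
  }
  # Shannon: band-limited with a flat passband of width 1.5 centred at 1
  wfs <- ctgnet:::waveletFunction("shan")
  t <- seq(-wfs$support, wfs$support, by = 0.01)
  psi <- wfs$psi(t)
  n_pad <- 2^16
  spec <- Mod(stats::fft(c(psi, complex(real = numeric(n_pad - length(psi))))))
  freqs <- (seq_len(n_pad %/% 2) - 1) / (n_pad * 0.01)
  inband <- freqs > 0.4 & freqs < 1.6
  outband <- freqs > 2.2
  expect_gt(mean(spec[inband]), 50 * mean(spec[outband]))
  expect_equal(centreFrequency("shan"), 1.0)
})

test_that("the scale of maximum response obeys the centre-frequency relation", {
  f <- 0.05                       # 20-s period sinusoid at 1 Hz
  x <- sin(2 * pi * f * (0:1199))
  for (wv in c("mexh", "morl")) {
    params <- cwtParams(wv)
    co <- cwtCoefficients(x, params)
    # restrict to interior translations to dodge edge effects; divide out
    # the sqrt(a) carried by the L2-normalized kernel so the maximum of
    # |psi_hat(a * omega)| itself is located
    interior <- 300:900
    resp <- rowMeans(co[, interior]) / sqrt(params$scales)
    i <- which.max(resp)
    r <- resp[(i - 1):(i + 1)]
    delta <- 0.5 * (r[1] - r[3]) / (r[1] - 2 * r[2] + r[3])
    step <- params$scales[2] / params$scales[1]
    a_star <- params$scales[i] * step^delta
    a_expect <- centreFrequency(wv) / f
    expect_lt(abs(log(a_star / a_expect)), log(step) + 0.01)
  }
})

test_that("unknown wavelets are rejected with the supported list", {
  expect_error(cwtParams("db4"), "mexh, morl, shan, gaus8")
  x <- rnorm(300)
  expect_error(scalogram(x, structure(list(wavelet = "sym5",
                                           scales = 1:4),
                                      class = "CWTParams")),
               "mexh, morl, shan, gaus8")
})
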