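test_that("artifact removal masks exactly the out-of-range samples", {
  rec <- FHRRecord(c(120, 245, 140, 49))
  expect_equal(validMask(removeArtifacts(rec)), c(TRUE, FALSE, TRUE, FALSE))
  # boundary values 230 and 50 are kept
  rec2 <- FHRRecord(c(230, 50, 230.0001, 49.9999))
  expect_equal(validMask(removeArtifacts(rec2)), c(TRUE, TRUE, FALSE, FALSE))
  # all in range: identity
  rec3 <- FHRRecord(runif(100, 60, 220))
  expect_identical(removeArtifacts(rec3), rec3)
  expect_error(removeArtifacts(FHRRecord(numeric(0))), "empty")
})

test_that("cleaning is idempotent and loss grows by exactly the outlier count", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 400
    v <- runif(n, 60, 220)
    k <- sample(0:20, 1)
    out_idx <- sample(n, k)
    v[out_idx] <- sample(c(runif(k, 231, 300), runif(k, 1, 49)), k)
    rec <- FHRRecord(v)
    c1 <- removeArtifacts(rec)
    expect_equal(signalLoss(c1), k / n)
    expect_identical(removeArtifacts(c1), c1)
  }
})

test_that("signal loss is the invalid fraction with typed edge cases", {
  expect_equal(signalLoss(rep(TRUE, 10)), 0)
  expect_equal(signalLoss(rep(FALSE, 10)), 1)
  expect_equal(signalLoss(c(rep(FALSE, 30), rep(TRUE, 30))), 0.5)
  expect_error(signalLoss(logical(0)), "empty")
})

test_that("start adjustment finds the first 5-min window under 50% loss", {
  rate <- 4
  # fully clean record starts at 0
  rec <- maskedRecord(rep(140, 30 * 60 * rate), rep(TRUE, 30 * 60 * rate))
  expect_equal(adjustStart(rec), 0)
  # first 10 minutes invalid: window at t has loss (10 - t)/5; first t with
  # loss < 0.5 on the 1-min grid is t = 8
  mask <- c(rep(FALSE, 10 * 60 * rate), rep(TRUE, 20 * 60 * rate))
  rec2 <- maskedRecord(rep(140, length(mask)), mask)
  expect_equal(adjustStart(rec2), 8)
  # fully invalid record is unusable
  rec3 <- maskedRecord(rep(140, 10 * 60 * rate), rep(FALSE, 10 * 60 * rate))
  expect_true(is.na(adjustStart(rec3)))
  expect_error(adjustStart(maskedRecord(rep(140, 100), rep(TRUE, 100))),
               "shorter")
})

test_that("segment extraction enforces the strict 50% quality filter", {
  rate <- 4; n20 <- 20 * 60 * rate
  rec <- maskedRecord(rep(140, n20), rep(TRUE, n20))
  seg <- extractSegment(rec, 0)
  expect_s4_class(seg, "FHRSegment")
  expect_equal(signalLoss(seg), 0)
  # exactly 50% loss is rejected (strictly less than)
  half <- maskedRecord(rep(140, n20), rep(c(TRUE, FALSE), n20 / 2))
  rej <- extractSegment(half, 0)
  expect_s3_class(rej, "segmentRejection")
  expect_equal(rej$loss, 0.5)
  expect_error(extractSegment(rec, 5), "exceeds")
})

test_that("a constructed cohort filters to the known survivor count", {
  rate <- 4; n20 <- 20 * 60 * rate
  losses <- c(rep(0.1, 6), rep(0.6, 4))
  survivors <- vapply(seq_along(losses), function(i) {
    mask <- rep(TRUE, n20)
    mask[seq_len(round(losses[i] * n20))] <- FALSE
    !inherits(extractSegment(maskedRecord(rep(140, n20), mask), 0),
              "segmentRejection")
  }, TRUE)
  expect_equal(sum(survivors), 6)
})

test_that("downsampling produces exact shapes and block means of valid samples", {
  seg <- constSegment(140)
  ds <- downsampleFHR(seg, 0.25)
  expect_equal(length(fhrValues(ds)), 300)   # 20 min -> 300 time steps
  expect_equal(samplingRate(ds), 0.25)
  expect_true(all(fhrValues(ds) == 140))
  ds1 <- downsampleFHR(seg, 1)
  expect_equal(length(fhrValues(ds1)), 1200)
  # block {120, 124, invalid, invalid} -> mean of valid members
  vals <- rep(c(120, 124, 130, 131), 300 * 4)[1:4800]
  seg2 <- gappySegment(vals, invalid_idx = which(seq_len(4800) %% 4 %in% c(3, 0)))
  d <- downsampleFHR(seg2, 1)
  expect_equal(fhrValues(d)[1], 122)
  expect_true(validMask(d)[1])
  # all-invalid block becomes an invalid output sample
  seg3 <- gappySegment(rep(140, 4800), invalid_idx = 1:4)
  d3 <- downsampleFHR(seg3, 1)
  expect_false(validMask(d3)[1])
  expect_error(downsampleFHR(seg, 3), "divide")
})

test_that("downsample then upsample-by-repetition preserves block means", {
  set.seed(7)
  seg <- FHRSegment(runif(4800, 110, 160), rate = 4)
  ds <- downsampleFHR(seg, 0.25)
  up <- rep(fhrValues(ds), each = 16)
  blocks <- matrix(fhrValues(seg), nrow = 16)
  expect_equal(up, rep(colMeans(blocks), each = 16), tolerance = 1e-12)
})

test_that("z-score standardization handles fit, params and degenerate sigma", {
  z <- standardize(c(1, 2, 3), "fit")
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(as.numeric(standardize(150, list(mu = 140, sigma = 5))), 2)
  expect_equal(as.numeric(standardize(rep(7, 5), "fit")), rep(0, 5))
  expect_error(standardize(c(1, NA)), "finite")
})

test_that("the cleaning pipeline never emits a segment at or above 50% loss and reduces mean loss", {
  p <- simParams(duration = 30, artifact_rate = 4, seed = 1)
  raw_loss <- c(); post_loss <- c()
  for (s in 1:12) {
    p$seed <- s
    rec <- simulateRecord(p, 0)
    out <- preprocessRecord(rec)
    raw_loss <- c(raw_loss, out$loss_raw)
    if (!is.null(out$segment)) {
      expect_lt(signalLoss(out$segment), 0.5)
      post_loss <- c(post_loss, out$loss_post)
    }
  }
  expect_gt(length(post_loss), 0)
  expect_lt(mean(post_loss), mean(raw_loss))
})
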