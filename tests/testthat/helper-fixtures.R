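# Shared fixture builders. Everything is generated in code; no files.

# clean constant-rate segment
constSegment <- function(bpm = 140, minutes = 20, rate = 4, outcome = 0) {
  FHRSegment(rep(bpm, minutes * 60 * rate), rate = rate, outcome = outcome)
}

# segment with a specified invalid index set
gappySegment <- function(values, invalid_idx, rate = 4) {
  mask <- rep(TRUE, length(values))
  mask[invalid_idx] <- FALSE
  FHRSegment(values, validMask = mask, rate = rate,
             duration = length(values) / rate / 60)
}

# record with an explicit mask
maskedRecord <- function(values, mask, rate = 4, outcome = 0) {
  FHRRecord(values, validMask = mask, rate = rate, outcome = outcome)
}

# AR(1) sample path
ar1Path <- function(n, phi = 0.9, sd = 1, seed = 1) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = sd))
}

# clean simulated params for fast tests
cleanSimParams <- function(...) {
  simParams(duration = 20, dropout_enter_prob = 0, artifact_rate = 0, ...)
}

# brute-force ROC threshold sweep oracles (independent of the package's
# cumulative-sum implementation)
bruteRoc <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(c(Inf, ths), function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0) / sum(labels == 0),
      tpr = sum(pred & labels == 1) / sum(labels == 1))
  }, c(fpr = 0, tpr = 0)))
  as.data.frame(pts)
}

brutePauc <- function(labels, scores, fpr_max = 0.1) {
  roc <- bruteRoc(labels, scores)     # ordered along the threshold sweep
  area <- 0
  for (i in 2:nrow(roc)) {
    f1 <- roc$fpr[i - 1]; f2 <- roc$fpr[i]
    t1 <- roc$tpr[i - 1]; t2 <- roc$tpr[i]
    if (f1 >= fpr_max) break
    if (f2 > fpr_max) {               # clip the straddling segment
      t2 <- t1 + (t2 - t1) * (fpr_max - f1) / (f2 - f1)
      f2 <- fpr_max
    }
    area <- area + (f2 - f1) * (t1 + t2) / 2
  }
  area / fpr_max
}

bruteSensAtSpec <- function(labels, scores, specificity = 0.95) {
  ths <- c(sort(unique(scores)), Inf)
  best <- 0
  for (th in ths) {
    pred <- scores >= th
    fpr <- sum(pred & labels == 0) / sum(labels == 0)
    if (fpr <= 1 - specificity)
      best <- max(best, sum(pred & labels == 1) / sum(labels == 1))
  }
  best
}
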