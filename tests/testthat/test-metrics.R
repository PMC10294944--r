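test_that("partial AUC has the right extremes and chance level", {
  y <- rep(c(0, 1), each = 20)
  perfect <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  expect_equal(pauc(y, perfect), 1)
  expect_equal(pauc(y, 1 - perfect), 0)
  expect_equal(sensitivityAtSpecificity(y, perfect), 1)
  expect_error(pauc(rep(1, 5), runif(5)), "classes")
  expect_error(pauc(y, perfect, fpr_max = 0), "fpr_max")
})

test_that("pauc and sensitivity match brute-force threshold sweeps on hand-set scores", {
  labels <- c(1, 0, 1, 0, 0, 1, 0, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.65, 0.6, 0.55, 0.5, 0.3, 0.2, 0.1)
  expect_equal(pauc(labels, scores, 0.1), brutePauc(labels, scores, 0.1),
               tolerance = 1e-4)
  expect_equal(sensitivityAtSpecificity(labels, scores, 0.95),
               bruteSensAtSpec(labels, scores, 0.95))
  # randomised cases with ties
  set.seed(12)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)      # induces ties
    for (fm in c(0.1, 0.25, 1)) {
      expect_equal(pauc(labels, scores, fm),
                   brutePauc(labels, scores, fm), tolerance = 2e-4)
    }
    expect_equal(sensitivityAtSpecificity(labels, scores),
                 bruteSensAtSpec(labels, scores))
  }
})

test_that("pauc with fpr_max = 1 equals the full AUC", {
  set.seed(13)
  for (i in 1:10) {
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- runif(30)
    full <- pauc(labels, scores, 1)
    # independent full-AUC oracle: the rank-sum (Mann-Whitney) statistic
    r <- rank(scores)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    auc_mw <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(full, auc_mw, tolerance = 1e-9)
  }
})

test_that("pauc agrees with pROC partial AUC as an independent cross-check", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- rbinom(200, 1, 0.3)
  scores <- runif(200) + 0.5 * labels
  ours <- pauc(labels, scores, 0.1)
  ref <- suppressMessages(as.numeric(
    pROC::auc(labels, scores, partial.auc = c(1, 0.9),
              partial.auc.focus = "specificity")))
  expect_equal(ours, ref / 0.1, tolerance = 1e-6)
  expect_equal(pauc(labels, scores, 1),
               suppressMessages(as.numeric(pROC::auc(labels, scores))),
               tolerance = 1e-9)
})

test_that("metrics are invariant under strictly monotone score transforms", {
  set.seed(15)
  labels <- rbinom(50, 1, 0.4)
  scores <- runif(50)
  for (tf in list(function(s) s^3, function(s) exp(2 * s),
                  function(s) qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)))) {
    expect_equal(pauc(labels, tf(scores)), pauc(labels, scores))
    expect_equal(sensitivityAtSpecificity(labels, tf(scores)),
                 sensitivityAtSpecificity(labels, scores))
  }
})

test_that("random scores score near chance in the low-FPR band", {
  set.seed(16)
  sens <- vapply(1:100, function(i) {
    labels <- rep(c(0, 1), each = 250)
    scores <- runif(500)
    sensitivityAtSpecificity(labels, scores, 0.95)
  }, 0)
  expect_lt(abs(mean(sens) - 0.05), 0.02)
})

test_that("precision/recall/F1 follow the contingency table with zero-denominator flags", {
  pr <- prf(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(pr[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))
  # no positive predictions: flagged zero precision
  pr2 <- prf(c(1, 1, 0), c(0.1, 0.2, 0.3), threshold = 0.9)
  expect_equal(pr2$precision, 0)
  expect_equal(pr2$recall, 0)
  expect_true("precision" %in% attr(pr2, "flagged"))
  # TP=5, FP=353, FN=3
  labels <- c(rep(1, 5), rep(0, 353), rep(1, 3), rep(0, 100))
  scores <- c(rep(0.9, 5), rep(0.9, 353), rep(0.1, 3), rep(0.1, 100))
  pr3 <- prf(labels, scores)
  expect_equal(pr3$precision, 5 / 358)
  expect_equal(pr3$recall, 5 / 8)
  expect_equal(pr3$f1, 2 * (5 / 358) * (5 / 8) / (5 / 358 + 5 / 8))
})

test_that("ROC points are monotone and the report aggregates all metrics", {
  set.seed(17)
  labels <- rbinom(60, 1, 0.5)
  scores <- runif(60)
  roc <- rocPoints(labels, scores)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  rep <- evalReport(labels, scores)
  expect_s3_class(rep, "EvalReport")
  for (mn in c("pauc_std", "sens_at_95spec", "auc", "precision", "recall",
               "f1"))
    expect_true(rep[[mn]] >= 0 && rep[[mn]] <= 1)
})
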