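#' ROC points from labels and scores
#'
#' One point per distinct score threshold (ties grouped), anchored at
#' (0, 0) and (1, 1); both coordinates are non-decreasing.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, larger = more positive.
#' @return \code{data.frame} with columns \code{fpr}, \code{tpr}.
#' @export
rocPoints <- function(labels, scores) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  data.frame(fpr = c(0, fp[keep] / n_neg), tpr = c(0, tp[keep] / n_pos))
}

#' Standardized partial AUC over a low false-positive-rate band
#'
#' Trapezoidal area under the ROC curve restricted to
#' FPR in [0, \code{fpr_max}] (with linear interpolation at the band
#' boundary), divided by the band width, so a perfect classifier scores 1
#' and chance scores \code{fpr_max / 2} (0.05 for the default 10% band).
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores finite numeric scores.
#' @param fpr_max band upper limit (default 0.1); \code{fpr_max = 1}
#'   recovers the full AUC.
#' @return standardized partial AUC in [0, 1].
#' @examples
#' pauc(c(0, 0, 1, 1), c(.1, .2, .8, .9))   # separable: 1
#' @export
pauc <- function(labels, scores, fpr_max = 0.1) {
  roc <- rocPoints(labels, scores)
  fpr <- roc$fpr; tpr <- roc$tpr
  if (fpr_max <= 0 || fpr_max > 1) stop("fpr_max must lie in (0, 1]")
  # interpolate the curve exactly at the boundary
  if (!any(fpr == fpr_max)) {
    hi <- which(fpr > fpr_max)[1]
    if (!is.na(hi)) {
      lo <- hi - 1L
      w <- (fpr_max - fpr[lo]) / (fpr[hi] - fpr[lo])
      fpr <- c(fpr[1:lo], fpr_max)
      tpr <- c(tpr[1:lo], tpr[lo] + w * (tpr[hi] - tpr[lo]))
    }
  } else {
    cut <- max(which(fpr == fpr_max))
    fpr <- fpr[1:cut]; tpr <- tpr[1:cut]
  }
  keep <- fpr <= fpr_max
  fpr <- fpr[keep]; tpr <- tpr[keep]
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  area / fpr_max
}

#' Sensitivity at a fixed specificity
#'
#' Maximum true positive rate over all thresholds whose false positive
#' rate does not exceed \code{1 - specificity}.
#'
#' @inheritParams pauc
#' @param specificity target specificity (default 0.95, i.e. a 5% FPR
#'   budget).
#' @return TPR fraction in [0, 1].
#' @export
sensitivityAtSpecificity <- function(labels, scores, specificity = 0.95) {
  roc <- rocPoints(labels, scores)
  ok <- roc$fpr <= 1 - specificity
  if (!any(ok)) return(0)
  max(roc$tpr[ok])
}

#' Precision, recall and F1 at a fixed threshold
#'
#' Standard definitions at \code{threshold}; when a denominator is zero
#' the metric is returned as 0 with the \code{flagged} attribute naming
#' it.
#'
#' @inheritParams pauc
#' @param threshold classification threshold on the scores (default 0.5).
#' @return List with \code{precision}, \code{recall}, \code{f1},
#'   \code{threshold}.
#' @export
prf <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  flagged <- character(0)
  precision <- if (tp + fp == 0) { flagged <- c(flagged, "precision"); 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { flagged <- c(flagged, "recall"); 0 } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) { flagged <- c(flagged, "f1"); 0 } else
    2 * precision * recall / (precision + recall)
  out <- list(precision = precision, recall = recall, f1 = f1,
              threshold = threshold)
  if (length(flagged)) attr(out, "flagged") <- flagged
  out
}

#' Full evaluation report for one model on one test set
#'
#' @inheritParams prf
#' @return List of class \code{"EvalReport"}: \code{pauc_std},
#'   \code{sens_at_95spec}, \code{auc}, \code{precision}, \code{recall},
#'   \code{f1}, \code{roc}, \code{threshold}.
#' @export
evalReport <- function(labels, scores, threshold = 0.5) {
  pr <- prf(labels, scores, threshold)
  structure(list(pauc_std = pauc(labels, scores, 0.1),
                 sens_at_95spec = sensitivityAtSpecificity(labels, scores, 0.95),
                 auc = pauc(labels, scores, 1),
                 precision = pr$precision, recall = pr$recall, f1 = pr$f1,
                 roc = rocPoints(labels, scores), threshold = threshold),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(paste0("EvalReport: PAUC(0-10%% FPR, standardized) %.3f | ",
                     "TPR@95%% spec %.3f | AUC %.3f\n",
                     "            precision %.3f | recall %.3f | F1 %.3f ",
                     "(threshold %.2f)\n"),
              x$pauc_std, x$sens_at_95spec, x$auc, x$precision, x$recall,
              x$f1, x$threshold))
  invisible(x)
}
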