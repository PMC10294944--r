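#' Short-term variability (STV) of an FHR segment
#'
#' Dawes-Redman-style estimator: the FHR is converted to beat intervals
#' (60000 / bpm, in milliseconds), intervals are averaged over 3.75-second
#' epochs, and the STV is the mean absolute difference between successive
#' epoch means. At 0.25 Hz one sample spans 4 s, approximately one epoch,
#' so the per-sample differences are used directly.
#'
#' @param segment an imputed \linkS4class{FHRSegment} (or numeric bpm
#'   vector with a \code{rate} attribute supplied via \code{rate}).
#' @param rate sampling rate override for plain vectors.
#' @return STV in milliseconds (non-negative).
#' @examples
#' stv(FHRSegment(rep(140, 4800), rate = 4))       # 0
#' @export
stv <- function(segment, rate = NULL) {
  if (is(segment, "FHRSegment") || is(segment, "FHRRecord")) {
    x <- segment@values[segment@validMask]
    rate <- segment@rate
  } else {
    x <- segment
    if (is.null(rate)) stop("rate must be given for plain vectors")
  }
  if (any(x <= 0)) stop("non-positive bpm values")
  intervals <- 60000 / x
  ep <- max(1L, round(3.75 * rate))
  n_ep <- length(intervals) %/% ep
  if (n_ep < 2) stop("segment too short for STV estimation")
  em <- colMeans(matrix(intervals[seq_len(n_ep * ep)], nrow = ep))
  mean(abs(diff(em)))
}

#' Baseline FHR level of a segment
#'
#' 10%-trimmed mean of the segment: the trimming excludes transient
#' accelerations and decelerations so the estimate tracks the
#' non-accelerative level. The clinical grouping cut used in the post-hoc
#' analysis is 150 bpm.
#'
#' @inheritParams stv
#' @param trim trimming fraction per tail.
#' @return baseline in bpm, within the observed value range.
#' @export
fhrBaseline <- function(segment, trim = 0.1) {
  x <- if (is(segment, "FHRSegment") || is(segment, "FHRRecord"))
    segment@values[segment@validMask] else segment
  mean(x, trim = trim)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties. Zero-variance input has
#' no defined rank correlation: \code{NA} is returned with the
#' \code{flagged} attribute set.
#'
#' @param a,b equal-length numeric vectors (length >= 3).
#' @return rho in [-1, 1], or flagged \code{NA}.
#' @export
spearmanRho <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(structure(NA_real_, flagged = "zero-variance input"))
  stats::cor(a, b, method = "spearman")
}

#' Quartile grouping of model predictions
#'
#' Splits predictions at their own 25th and 75th percentiles: low
#' (<= 25th), high (>= 75th), medium (strictly between). When the two
#' percentiles coincide (near-constant predictions) the strict-inequality
#' rule leaves every sample medium; this degenerate case is flagged.
#'
#' @param predictions probability vector (length >= 4).
#' @return factor with levels \code{low}, \code{medium}, \code{high};
#'   attribute \code{breaks} holds the two percentiles.
#' @export
quartileGroups <- function(predictions) {
  if (length(predictions) < 4) stop("need at least 4 predictions")
  q <- stats::quantile(predictions, c(0.25, 0.75), names = FALSE)
  if (q[1] == q[2]) {
    g <- factor(rep("medium", length(predictions)),
                levels = c("low", "medium", "high"))
    attr(g, "breaks") <- q
    attr(g, "flagged") <- "degenerate quartiles; all samples medium"
    return(g)
  }
  lab <- ifelse(predictions <= q[1], "low",
                ifelse(predictions >= q[2], "high", "medium"))
  g <- factor(lab, levels = c("low", "medium", "high"))
  attr(g, "breaks") <- q
  g
}

#' Correlation of predictions with pre-imputation gap statistics
#'
#' Spearman rho of the model predictions against each of the four gap
#' statistics (loss fraction, number of gaps, longest gap, location of
#' the longest gap), per outcome class.
#'
#' @param predictions probability vector.
#' @param gap_stats list of \code{\link{gapStats}} results aligned with
#'   \code{predictions}.
#' @param labels optional 0/1 outcome per sample; without labels a single
#'   pooled row is reported.
#' @return data.frame with one row per class (an absent class is
#'   reported as a flagged all-\code{NA} row) and columns
#'   \code{signal_loss}, \code{n_gaps}, \code{longest_gap},
#'   \code{gap_location}.
#' @export
signalLossReport <- function(predictions, gap_stats, labels = NULL) {
  stopifnot(length(predictions) == length(gap_stats))
  feats <- data.frame(
    signal_loss = vapply(gap_stats, `[[`, 0, "loss_fraction"),
    n_gaps = vapply(gap_stats, function(g) as.numeric(g$n_gaps), 0),
    longest_gap = vapply(gap_stats, function(g) as.numeric(g$longest_gap), 0),
    gap_location = vapply(gap_stats, `[[`, 0, "longest_gap_location"))
  one_row <- function(idx) {
    if (length(idx) < 3)
      return(as.data.frame(as.list(stats::setNames(rep(NA_real_, 4),
                                                   names(feats)))))
    as.data.frame(lapply(feats[idx, ], function(col)
      as.numeric(spearmanRho(predictions[idx], col))))
  }
  if (is.null(labels)) {
    out <- one_row(seq_along(predictions))
    rownames(out) <- "all"
  } else {
    out <- rbind(one_row(which(labels == 1)), one_row(which(labels == 0)))
    rownames(out) <- c("severe_compromise", "no_compromise")
    if (!any(labels == 1)) attr(out, "flagged") <- "positive class absent"
    if (!any(labels == 0)) attr(out, "flagged") <- "negative class absent"
  }
  out
}

#' Clinical-feature attribution of model predictions
#'
#' Groups test-set predictions into prediction quartile groups and
#' tabulates the proportion of clinically low-STV segments
#' (STV <= \code{stv_cut} ms) and high-baseline segments
#' (>= \code{baseline_cut} bpm) in each group. The clinically expected
#' pattern is an enrichment of low-STV segments among high predictions.
#'
#' @param predictions probability vector.
#' @param stv_values STV (ms) per segment.
#' @param baseline_values baseline (bpm) per segment.
#' @param stv_cut clinical low-STV threshold (3 ms).
#' @param baseline_cut baseline grouping threshold (150 bpm).
#' @return data.frame, one row per prediction group, with group size and
#'   the low-STV / high-baseline proportions.
#' @export
clinicalAttribution <- function(predictions, stv_values, baseline_values,
                                stv_cut = 3, baseline_cut = 150) {
  g <- quartileGroups(predictions)
  do.call(rbind, lapply(levels(g), function(lv) {
    idx <- g == lv
    data.frame(group = lv, n = sum(idx),
               prop_low_stv = if (any(idx)) mean(stv_values[idx] <= stv_cut)
                              else NA_real_,
               prop_high_baseline = if (any(idx))
                 mean(baseline_values[idx] >= baseline_cut) else NA_real_)
  }))
}
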