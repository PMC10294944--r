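#' Remove extreme-outlier artifacts from an FHR record
#'
#' First cleaning stage: samples above 230 bpm or below 50 bpm are marked
#' invalid (the monitor cannot be reading the fetus there). Exactly 230 and
#' exactly 50 are kept; previously invalid samples stay invalid; values are
#' untouched so the raw trace remains inspectable.
#'
#' @param record an \linkS4class{FHRRecord} at its native rate.
#' @return The record with an updated validity mask.
#' @examples
#' rec <- FHRRecord(c(120, 245, 140, 49))
#' validMask(removeArtifacts(rec))
#' @export
removeArtifacts <- function(record) {
  stopifnot(is(record, "FHRRecord"))
  if (length(record@values) == 0L) stop("empty record")
  bad <- record@values > 230 | record@values < 50
  record@validMask <- record@validMask & !bad
  record
}

#' Adjust the start time of a record for signal quality
#'
#' Slides a 5-minute window along the record on a 1-minute grid and returns
#' the first offset whose window has signal loss strictly below 50%. A
#' record with no qualifying start is unusable and is excluded from the
#' cohort (returned as \code{NA}).
#'
#' @param record an \linkS4class{FHRRecord} of at least 5 minutes.
#' @param window_min quality window length in minutes.
#' @param stride_min grid stride in minutes.
#' @param max_loss admissible loss threshold (strict inequality).
#' @return Offset in minutes, or \code{NA_real_} when unusable.
#' @export
adjustStart <- function(record, window_min = 5, stride_min = 1, max_loss = 0.5) {
  stopifnot(is(record, "FHRRecord"))
  n <- length(record@values)
  w <- round(window_min * 60 * record@rate)
  s <- round(stride_min * 60 * record@rate)
  if (n < w) stop("record shorter than the quality window")
  for (start in seq.int(1L, n - w + 1L, by = s)) {
    if (signalLoss(record@validMask[start:(start + w - 1L)]) < max_loss)
      return((start - 1L) / record@rate / 60)
  }
  NA_real_
}

#' Extract a fixed-duration segment, subject to the quality filter
#'
#' Cuts a window of \code{duration} minutes starting at \code{offset} and
#' admits it only if its signal loss is strictly below 50%; otherwise a
#' typed rejection carrying the measured loss is returned.
#'
#' @param record an \linkS4class{FHRRecord}.
#' @param offset window start in minutes (normally from
#'   \code{\link{adjustStart}}).
#' @param duration window duration in minutes (default 20).
#' @param max_loss admissible loss threshold (strict inequality).
#' @return An \linkS4class{FHRSegment}, or an object of class
#'   \code{"segmentRejection"} with elements \code{loss} and
#'   \code{parent_id}.
#' @export
extractSegment <- function(record, offset, duration = 20, max_loss = 0.5) {
  stopifnot(is(record, "FHRRecord"))
  if (is.na(offset)) stop("offset is NA (record unusable)")
  n <- length(record@values)
  start <- round(offset * 60 * record@rate) + 1L
  len <- round(duration * 60 * record@rate)
  if (start + len - 1L > n) stop("window exceeds the end of the record")
  idx <- start:(start + len - 1L)
  loss <- signalLoss(record@validMask[idx])
  if (loss >= max_loss) {
    return(structure(list(loss = loss, parent_id = record@recordId),
                     class = "segmentRejection"))
  }
  FHRSegment(record@values[idx], validMask = record@validMask[idx],
             rate = record@rate, parentId = record@recordId,
             startOffset = offset, duration = duration,
             outcome = record@outcome)
}

#' Downsample a record or segment by block averaging
#'
#' Each output sample is the mean of the valid source samples in its block;
#' a block with no valid sample yields an invalid output sample. The target
#' rate must divide the source rate.
#'
#' @param x an \linkS4class{FHRRecord} or \linkS4class{FHRSegment}.
#' @param target_rate output rate in Hz (e.g. 0.25 for the 1D networks,
#'   1 for the time-frequency images).
#' @return Same class as the input, at \code{target_rate}.
#' @examples
#' seg <- FHRSegment(rep(140, 4800), rate = 4)
#' length(fhrValues(downsampleFHR(seg, 0.25)))  # 300 time steps
#' @export
downsampleFHR <- function(x, target_rate) {
  stopifnot(is(x, "FHRRecord") || is(x, "FHRSegment"))
  factor <- x@rate / target_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop(sprintf("target rate %g Hz does not divide source rate %g Hz",
                 target_rate, x@rate))
  factor <- as.integer(round(factor))
  n_out <- length(x@values) %/% factor
  idx <- rep(seq_len(n_out), each = factor)
  v <- x@values[seq_len(n_out * factor)]
  m <- x@validMask[seq_len(n_out * factor)]
  vm <- ifelse(m, v, 0)
  counts <- as.vector(rowsum(as.numeric(m), idx))
  sums <- as.vector(rowsum(vm, idx))
  out_vals <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  out_mask <- counts > 0
  if (is(x, "FHRSegment")) {
    new("FHRSegment", parentId = x@parentId, startOffset = x@startOffset,
        duration = x@duration, values = out_vals, validMask = out_mask,
        rate = target_rate, outcome = x@outcome)
  } else {
    new("FHRRecord", values = out_vals, validMask = out_mask,
        rate = target_rate, outcome = x@outcome, recordId = x@recordId)
  }
}

#' z-score standardization
#'
#' With \code{params = "fit"} the mean and standard deviation are estimated
#' from \code{x} itself (per-segment standardization, which avoids any
#' train/test leakage); otherwise the supplied \code{mu}/\code{sigma} are
#' applied elementwise as \code{(x - mu) / sigma}. A zero sigma yields an
#' all-zero output rather than NaNs.
#'
#' @param x finite numeric vector (imputed values).
#' @param params \code{"fit"} or a list with \code{mu} and \code{sigma}.
#' @return Numeric vector; when fitted, with attributes \code{mu} and
#'   \code{sigma}.
#' @examples
#' standardize(c(150), list(mu = 140, sigma = 5))
#' @export
standardize <- function(x, params = "fit") {
  if (!all(is.finite(x))) stop("x must be finite (impute gaps first)")
  if (identical(params, "fit")) {
    mu <- mean(x)
    sigma <- stats::sd(x)
    if (!is.finite(sigma)) sigma <- 0
  } else {
    mu <- params$mu; sigma <- params$sigma
    if (sigma < 0) stop("sigma must be >= 0")
  }
  z <- if (sigma == 0) rep(0, length(x)) else (x - mu) / sigma
  attr(z, "mu") <- mu
  attr(z, "sigma") <- sigma
  z
}

#' Clean a raw record and extract its quality-controlled 20-min segment
#'
#' The full two-stage front end: artifact removal, start adjustment on the
#' 5-minute / 1-minute-stride grid, and quality-filtered segment
#' extraction.
#'
#' @param record raw \linkS4class{FHRRecord}.
#' @param duration segment duration in minutes.
#' @return A list with \code{segment} (\linkS4class{FHRSegment} or
#'   \code{NULL}), \code{offset}, \code{loss_raw} and \code{loss_post};
#'   \code{segment} is \code{NULL} when the record is unusable or rejected.
#' @export
preprocessRecord <- function(record, duration = 20) {
  loss_raw <- signalLoss(record)
  cleaned <- removeArtifacts(record)
  n_min <- length(cleaned@values) / cleaned@rate / 60
  if (n_min < duration)
    return(list(segment = NULL, offset = NA_real_, loss_raw = loss_raw,
                loss_post = NA_real_))
  offset <- adjustStart(cleaned)
  if (is.na(offset) || offset + duration > n_min)
    return(list(segment = NULL, offset = offset, loss_raw = loss_raw,
                loss_post = NA_real_))
  seg <- extractSegment(cleaned, offset, duration)
  if (inherits(seg, "segmentRejection"))
    return(list(segment = NULL, offset = offset, loss_raw = loss_raw,
                loss_post = seg$loss))
  list(segment = seg, offset = offset, loss_raw = loss_raw,
       loss_post = signalLoss(seg))
}
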