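#' @import methods
NULL

#' FHRRecord: a fetal heart rate trace with validity mask
#'
#' Container for one cardiotocogram fetal heart rate (FHR) channel: bpm
#' values sampled at a fixed rate, a logical validity mask (sensor dropout
#' and removed artifacts are \code{FALSE}), the birth-outcome label and a
#' record identifier. Masked-out entries are ignored by every statistic in
#' the package; gaps are encoded only in the mask, never as sentinel values.
#'
#' @slot values numeric vector of FHR values in beats per minute.
#' @slot validMask logical vector, same length as \code{values}.
#' @slot rate sampling rate in Hz.
#' @slot outcome integer, 1 = severe compromise at birth, 0 = none,
#'   \code{NA} = unknown.
#' @slot recordId character identifier.
#'
#' @aliases FHRRecord-class
#' @exportClass FHRRecord
setClass("FHRRecord",
  representation(
    values    = "numeric",
    validMask = "logical",
    rate      = "numeric",
    outcome   = "integer",
    recordId  = "character"
  ),
  prototype(rate = 4, outcome = NA_integer_, recordId = "record")
)

setValidity("FHRRecord", function(object) {
  msg <- NULL
  if (length(object@values) != length(object@validMask))
    msg <- c(msg, "values and validMask must have equal length")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (!is.na(object@outcome) && !object@outcome %in% c(0L, 1L))
    msg <- c(msg, "outcome must be 0, 1 or NA")
  if (any(object@validMask & !is.finite(object@values)))
    msg <- c(msg, "valid samples must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct an FHRRecord
#'
#' @param values numeric bpm vector.
#' @param validMask logical mask (defaults to the finite entries of
#'   \code{values}).
#' @param rate sampling rate in Hz (default 4).
#' @param outcome 0/1/NA outcome label.
#' @param recordId record identifier.
#' @return An \linkS4class{FHRRecord}.
#' @examples
#' rec <- FHRRecord(c(140, 141, NA, 139), rate = 4)
#' signalLoss(rec)
#' @export
FHRRecord <- function(values, validMask = NULL, rate = 4,
                      outcome = NA, recordId = "record") {
  values <- as.numeric(values)
  if (is.null(validMask)) validMask <- is.finite(values)
  new("FHRRecord", values = values, validMask = as.logical(validMask),
      rate = rate, outcome = as.integer(outcome), recordId = as.character(recordId))
}

#' FHRSegment: a fixed-duration window of an FHR record
#'
#' A 20-minute (by default) window cut from an \linkS4class{FHRRecord}, with
#' its provenance (parent identifier, start offset) retained so grouped
#' train/test splitting can keep all windows of one record together.
#'
#' @slot parentId identifier of the source record.
#' @slot startOffset window start within the record, minutes.
#' @slot duration window duration, minutes.
#' @slot values,validMask,rate as in \linkS4class{FHRRecord}.
#' @slot outcome outcome label inherited from the parent record.
#'
#' @aliases FHRSegment-class
#' @exportClass FHRSegment
setClass("FHRSegment",
  representation(
    parentId    = "character",
    startOffset = "numeric",
    duration    = "numeric",
    values      = "numeric",
    validMask   = "logical",
    rate        = "numeric",
    outcome     = "integer"
  ),
  prototype(startOffset = 0, duration = 20, rate = 4, outcome = NA_integer_)
)

setValidity("FHRSegment", function(object) {
  msg <- NULL
  if (length(object@values) != length(object@validMask))
    msg <- c(msg, "values and validMask must have equal length")
  n_expect <- round(object@duration * 60 * object@rate)
  if (length(object@values) != n_expect)
    msg <- c(msg, sprintf("length %d != duration * rate = %d",
                          length(object@values), n_expect))
  if (object@startOffset < 0) msg <- c(msg, "startOffset must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct an FHRSegment
#'
#' @param values,validMask,rate as in \code{\link{FHRRecord}}.
#' @param parentId source record identifier.
#' @param startOffset start of the window within the parent, minutes.
#' @param duration window duration in minutes.
#' @param outcome 0/1/NA outcome label.
#' @return An \linkS4class{FHRSegment}.
#' @export
FHRSegment <- function(values, validMask = NULL, rate = 4, parentId = "record",
                       startOffset = 0, duration = length(values) / rate / 60,
                       outcome = NA) {
  values <- as.numeric(values)
  if (is.null(validMask)) validMask <- is.finite(values)
  new("FHRSegment", values = values, validMask = as.logical(validMask),
      rate = rate, parentId = as.character(parentId),
      startOffset = startOffset, duration = duration,
      outcome = as.integer(outcome))
}

#' TFImage: a 128 x 128 time-frequency image
#'
#' Spectrogram or scalogram of a fully imputed 1 Hz FHR segment, resized to
#' 128 x 128 and min-max scaled to [0, 1]. The single plane is replicated to
#' three channels when fed to the 2D networks.
#'
#' @slot pixels 128 x 128 numeric matrix in [0, 1] (rows = frequency/scale,
#'   columns = time).
#' @slot kind "spectrogram" or "scalogram".
#' @slot params the generation parameters (an \code{stftParams} or
#'   \code{cwtParams} list).
#'
#' @aliases TFImage-class
#' @exportClass TFImage
setClass("TFImage",
  representation(pixels = "matrix", kind = "character", params = "list")
)

setValidity("TFImage", function(object) {
  msg <- NULL
  if (!identical(dim(object@pixels), c(128L, 128L)))
    msg <- c(msg, "pixels must be exactly 128 x 128")
  if (!all(is.finite(object@pixels)))
    msg <- c(msg, "pixels must be finite")
  if (min(object@pixels) < 0 || max(object@pixels) > 1 + 1e-12)
    msg <- c(msg, "pixels must lie in [0, 1]")
  if (!object@kind %in% c("spectrogram", "scalogram"))
    msg <- c(msg, "kind must be 'spectrogram' or 'scalogram'")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FHRRecord", function(object) {
  n <- length(object@values)
  cat(sprintf("FHRRecord '%s': %d samples at %g Hz (%.1f min), loss %.1f%%, outcome %s\n",
              object@recordId, n, object@rate, n / object@rate / 60,
              100 * mean(!object@validMask),
              ifelse(is.na(object@outcome), "unknown", object@outcome)))
})

setMethod("show", "FHRSegment", function(object) {
  cat(sprintf("FHRSegment of '%s' @ %g min: %.0f min at %g Hz, loss %.1f%%, outcome %s\n",
              object@parentId, object@startOffset, object@duration, object@rate,
              100 * mean(!object@validMask),
              ifelse(is.na(object@outcome), "unknown", object@outcome)))
})

setMethod("show", "TFImage", function(object) {
  cat(sprintf("TFImage (%s): 128 x 128, range [%.3f, %.3f]\n",
              object@kind, min(object@pixels), max(object@pixels)))
})
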