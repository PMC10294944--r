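#' Accessors for FHR containers
#'
#' @param object an \linkS4class{FHRRecord} or \linkS4class{FHRSegment}.
#' @return \code{fhrValues}: numeric bpm vector; \code{validMask}: logical
#'   mask; \code{samplingRate}: Hz; \code{outcomeLabel}: 0/1/NA;
#'   \code{recordId}: identifier of the record (for a segment, its parent).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fhrValues", function(object) standardGeneric("fhrValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("outcomeLabel", function(object) standardGeneric("outcomeLabel"))
#' @rdname accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))

#' @rdname accessors
setMethod("fhrValues", "FHRRecord", function(object) object@values)
#' @rdname accessors
setMethod("fhrValues", "FHRSegment", function(object) object@values)
#' @rdname accessors
setMethod("validMask", "FHRRecord", function(object) object@validMask)
#' @rdname accessors
setMethod("validMask", "FHRSegment", function(object) object@validMask)
#' @rdname accessors
setMethod("samplingRate", "FHRRecord", function(object) object@rate)
#' @rdname accessors
setMethod("samplingRate", "FHRSegment", function(object) object@rate)
#' @rdname accessors
setMethod("outcomeLabel", "FHRRecord", function(object) object@outcome)
#' @rdname accessors
setMethod("outcomeLabel", "FHRSegment", function(object) object@outcome)
#' @rdname accessors
setMethod("recordId", "FHRRecord", function(object) object@recordId)
#' @rdname accessors
setMethod("recordId", "FHRSegment", function(object) object@parentId)

#' Start offset of a segment within its parent record
#' @param object an \linkS4class{FHRSegment}.
#' @return offset in minutes.
#' @export
setGeneric("startOffset", function(object) standardGeneric("startOffset"))
#' @rdname startOffset
setMethod("startOffset", "FHRSegment", function(object) object@startOffset)

#' Pixel matrix of a time-frequency image
#' @param object a \linkS4class{TFImage}.
#' @return 128 x 128 numeric matrix in [0, 1].
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname imagePixels
setMethod("imagePixels", "TFImage", function(object) object@pixels)

#' Fraction of invalid samples
#'
#' Signal loss is the fraction of a trace (or mask) carrying no valid FHR
#' sample, after sensor dropout and artifact removal.
#'
#' @param object an \linkS4class{FHRRecord}, \linkS4class{FHRSegment} or a
#'   logical mask (\code{TRUE} = valid).
#' @return fraction in [0, 1].
#' @examples
#' signalLoss(c(TRUE, FALSE, TRUE, FALSE))
#' @export
setGeneric("signalLoss", function(object) standardGeneric("signalLoss"))

#' @rdname signalLoss
setMethod("signalLoss", "logical", function(object) {
  if (length(object) == 0L) stop("empty mask")
  mean(!object)
})
#' @rdname signalLoss
setMethod("signalLoss", "FHRRecord", function(object) signalLoss(object@validMask))
#' @rdname signalLoss
setMethod("signalLoss", "FHRSegment", function(object) signalLoss(object@validMask))
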