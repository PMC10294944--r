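#' Augmentation configuration
#'
#' Positive (severe-compromise) records are expanded by cutting additional
#' 20-minute windows from the first hour with 50% overlap (a factor of 4)
#' and then oversampling by a factor of 2, for an overall factor of 8.
#' Only windows below the signal-loss threshold qualify. A 60-minute trace
#' at a 10-minute stride admits five candidate starts; the first
#' \code{max_windows_per_record} (default 4, matching the stated expansion
#' factor) are retained.
#'
#' @param window_minutes window length, minutes.
#' @param stride_minutes stride between window starts, minutes (50%
#'   overlap).
#' @param max_windows_per_record cap on windows per record.
#' @param oversample_factor exact-duplicate oversampling factor.
#' @param quality_threshold admissible signal loss (strict inequality).
#' @return List of class \code{"AugmentConfig"}.
#' @export
augmentConfig <- function(window_minutes = 20, stride_minutes = 10,
                          max_windows_per_record = 4, oversample_factor = 2,
                          quality_threshold = 0.5) {
  if (stride_minutes > window_minutes) stop("stride must be <= window")
  if (max_windows_per_record < 1 || oversample_factor < 1)
    stop("factors must be >= 1")
  structure(list(window_minutes = window_minutes,
                 stride_minutes = stride_minutes,
                 max_windows_per_record = as.integer(max_windows_per_record),
                 oversample_factor = as.integer(oversample_factor),
                 quality_threshold = quality_threshold),
            class = "AugmentConfig")
}

#' Overlapping-window extraction from a positive first-hour record
#'
#' Cuts candidate 20-minute windows at the configured stride from the
#' record's adjusted start, keeps those passing the quality threshold, and
#' truncates to the per-record cap, preserving order. Applied to
#' positive-outcome records only; negative records pass through the
#' pipeline with their single adjusted-start segment.
#'
#' @param record a cleaned positive-outcome \linkS4class{FHRRecord}
#'   (nominally the first hour).
#' @param cfg an \code{\link{augmentConfig}}.
#' @param from_offset start of the first window, minutes (the adjusted
#'   start).
#' @return List of \linkS4class{FHRSegment}s (possibly empty, with a
#'   warning, when the record is shorter than one window).
#' @export
windowPositives <- function(record, cfg = augmentConfig(), from_offset = 0) {
  stopifnot(is(record, "FHRRecord"))
  n_min <- length(record@values) / record@rate / 60
  if (n_min < cfg$window_minutes) {
    warning("record shorter than one window; no segments extracted")
    return(list())
  }
  starts <- seq(from_offset, n_min - cfg$window_minutes,
                by = cfg$stride_minutes)
  out <- list()
  for (s in starts) {
    seg <- extractSegment(record, s, cfg$window_minutes,
                          max_loss = cfg$quality_threshold)
    if (!inherits(seg, "segmentRejection")) out[[length(out) + 1L]] <- seg
    if (length(out) >= cfg$max_windows_per_record) break
  }
  out
}

#' Oversample a segment list by exact duplication
#'
#' @param segments list of segments (or any objects).
#' @param factor each element appears exactly \code{factor} times.
#' @return List of length \code{length(segments) * factor}, duplicates
#'   adjacent to their originals.
#' @export
oversampleSegments <- function(segments, factor = 2) {
  if (factor < 1) stop("factor must be >= 1")
  if (length(segments) == 0L) return(list())
  rep(segments, each = as.integer(factor))
}

#' Positive-class weight from inverse class frequency
#'
#' The weighted binary cross-entropy penalises positive-class
#' misclassification by the ratio of negative to (augmented) positive
#' training samples. The raw ratio enters the loss; the rounded integer is
#' what gets reported.
#'
#' @param n_negative negative training sample count.
#' @param n_positive_augmented positive training sample count after
#'   augmentation.
#' @return The raw ratio, with attribute \code{rounded}.
#' @examples
#' classWeight(36799, 2611)   # rounds to 14
#' @export
classWeight <- function(n_negative, n_positive_augmented) {
  if (n_positive_augmented <= 0) stop("positive count must be > 0")
  if (n_negative <= 0) stop("negative count must be > 0")
  w <- n_negative / n_positive_augmented
  attr(w, "rounded") <- as.integer(round(w))
  w
}
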