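#' Write an FHR record to a two-column CSV with a JSON sidecar
#'
#' The CSV has columns \code{time_s} and \code{fhr_bpm}; invalid samples
#' are written as empty fields. A sidecar JSON (same path with a
#' \code{.json} extension) carries the sampling rate, outcome and record
#' id so the round trip is lossless.
#'
#' @param record an \linkS4class{FHRRecord}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRecord <- function(record, path) {
  stopifnot(is(record, "FHRRecord"))
  n <- length(record@values)
  vals <- ifelse(record@validMask, sprintf("%.4f", record@values), "")
  times <- sprintf("%.2f", (seq_len(n) - 1L) / record@rate)
  writeLines(c("time_s,fhr_bpm", paste(times, vals, sep = ",")), path)
  meta <- list(rate = record@rate, outcome = record@outcome,
               record_id = record@recordId)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecarPath <- function(path) sub("\\.csv$", ".json", path)

#' Read an FHR record written by \code{\link{writeRecord}}
#'
#' @param path CSV path (the JSON sidecar is read when present).
#' @return An \linkS4class{FHRRecord}; empty bpm fields become invalid
#'   samples. A malformed (non-numeric) bpm field raises an error naming
#'   the offending line.
#' @export
readRecord <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || !identical(header[1:2], c("time_s", "fhr_bpm")))
    stop("unexpected header in ", path)
  if (length(lines) < 2L) stop("record file has no data rows: ", path)
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  vals <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    raw <- if (length(p) >= 2) p[2] else ""
    if (raw == "") return(NA_real_)
    v <- suppressWarnings(as.numeric(raw))
    if (is.na(v))
      stop(sprintf("non-numeric fhr_bpm at line %d of %s: '%s'",
                   i + 1L, path, raw))
    v
  }, 0)
  rate <- 4; outcome <- NA; rid <- sub("\\.csv$", "", basename(path))
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    rate <- meta$rate
    outcome <- if (is.null(meta$outcome)) NA else meta$outcome
    if (!is.null(meta$record_id)) rid <- meta$record_id
  }
  FHRRecord(vals, validMask = !is.na(vals), rate = rate, outcome = outcome,
            recordId = rid)
}

#' Duration of a record in minutes
#' @param record an \linkS4class{FHRRecord}.
#' @return minutes.
#' @export
recordDuration <- function(record) {
  length(record@values) / record@rate / 60
}

#' Read a cohort manifest TSV
#' @param path manifest path (\code{record_id}, \code{path},
#'   \code{outcome} columns).
#' @param dir base directory for relative record paths.
#' @return data.frame manifest.
#' @export
readManifest <- function(path, dir = dirname(path)) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("record_id", "path", "outcome") %in% names(man)))
    stop("manifest must have record_id, path, outcome columns")
  rel <- !file.exists(man$path) & file.exists(file.path(dir, basename(man$path)))
  man$path[rel] <- file.path(dir, basename(man$path[rel]))
  man
}

#' Pipeline configuration
#'
#' Schema-validated nested configuration for \code{\link{runPipeline}};
#' unknown keys are rejected. Section defaults mirror each stage's own
#' defaults.
#'
#' @param simulate list: \code{n_records}, \code{prevalence},
#'   \code{params} (a \code{\link{simParams}}), optional
#'   \code{params_by_class}.
#' @param impute list: \code{method} in \{linear, ar, gp\}.
#' @param timefreq list: \code{kind} in \{none, spectrogram, scalogram\}
#'   plus the relevant params object.
#' @param augment an \code{\link{augmentConfig}}, or \code{NULL} to
#'   disable positive-class augmentation.
#' @param model a \code{\link{modelSpec}}.
#' @param train a \code{\link{trainConfig}}.
#' @param seed master seed fanned out to every stage.
#' @return List of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulate = list(n_records = 120, prevalence = 0.1,
                                           params = simParams(duration = 20)),
                           impute = list(method = "ar"),
                           timefreq = list(kind = "none"),
                           augment = augmentConfig(),
                           model = modelSpec("cnn_lstm_par"),
                           train = trainConfig(),
                           seed = 1L) {
  known_sim <- c("n_records", "prevalence", "params", "params_by_class")
  if (length(setdiff(names(simulate), known_sim)))
    stop("unknown simulate keys: ",
         paste(setdiff(names(simulate), known_sim), collapse = ", "))
  if (!impute$method %in% c("linear", "ar", "gp"))
    stop("impute$method must be linear, ar or gp")
  if (!timefreq$kind %in% c("none", "spectrogram", "scalogram"))
    stop("timefreq$kind must be none, spectrogram or scalogram")
  needs_img <- model$arch %in% c("cnn2d_residual", "multimodal")
  if (needs_img && timefreq$kind == "none")
    stop("architecture ", model$arch, " needs timefreq$kind != 'none'")
  structure(list(simulate = simulate, impute = impute, timefreq = timefreq,
                 augment = augment, model = model, train = train,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unserializeClean(config)), tmp)
  unname(tools::md5sum(tmp))
}

# strip closures/classes so the config serialises stably to YAML
unserializeClean <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unserializeClean))
  if (is.function(x)) return("<function>")
  x
}
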