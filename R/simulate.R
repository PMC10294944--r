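#' Simulation parameters for synthetic FHR records
#'
#' Bundles the knobs of the synthetic cardiotocogram generator: baseline
#' level and slow drift, short-term variability (STV) of the beat
#' intervals, acceleration/deceleration event rates, the two-state Markov
#' dropout process, and artifact injection.
#'
#' The generator is built so that the package's own STV estimator
#' (\code{\link{stv}}) recovers \code{stv_target} on clean traces: beat
#' intervals receive independent per-epoch (3.75 s) Gaussian perturbations
#' whose scale is calibrated analytically against the mean-absolute-
#' successive-difference statistic, with the baseline random walk's
#' contribution subtracted.
#'
#' @param baseline_mean mean FHR baseline, bpm (normal range 110-160).
#' @param baseline_sd stationary standard deviation of the slow baseline
#'   random walk, bpm.
#' @param stv_target short-term beat-interval variability target, ms.
#' @param accel_rate accelerations per hour (+15 bpm smooth bumps, 1-3 min).
#' @param decel_rate decelerations per hour (smooth dips of
#'   \code{decel_depth} bpm, 1-3 min).
#' @param decel_depth deceleration depth, bpm.
#' @param dropout_enter_prob per-sample probability of entering signal
#'   dropout; the stationary loss fraction is
#'   \code{enter / (enter + exit)}.
#' @param dropout_exit_prob per-sample probability of leaving dropout.
#' @param artifact_rate injected artifact episodes per hour: spikes above
#'   230 bpm, drops below 50 bpm, and maternal-heart-rate capture episodes
#'   at about half the fetal rate.
#' @param duration trace duration, minutes (>= 20 for pipeline use).
#' @param seed integer seed; the trace is a deterministic function of
#'   (params, seed, outcome).
#' @param pos_stv_factor multiplier applied to \code{stv_target} for
#'   positive-outcome (severe compromise) records; low STV is the clinical
#'   marker being emulated.
#' @param pos_decel_factor multiplier applied to \code{decel_rate} for
#'   positive-outcome records.
#' @return A validated list of class \code{"SimParams"}.
#' @examples
#' p <- simParams(duration = 20, dropout_enter_prob = 0, artifact_rate = 0)
#' rec <- simulateRecord(p, outcome = 0)
#' signalLoss(rec)
#' @export
simParams <- function(baseline_mean = 140, baseline_sd = 5, stv_target = 6,
                      accel_rate = 3, decel_rate = 1, decel_depth = 20,
                      dropout_enter_prob = 0.00617, dropout_exit_prob = 0.01667,
                      artifact_rate = 1, duration = 30, seed = 1L,
                      pos_stv_factor = 0.42, pos_decel_factor = 2) {
  p <- list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            stv_target = stv_target, accel_rate = accel_rate,
            decel_rate = decel_rate, decel_depth = decel_depth,
            dropout_enter_prob = dropout_enter_prob,
            dropout_exit_prob = dropout_exit_prob,
            artifact_rate = artifact_rate, duration = duration,
            seed = as.integer(seed), pos_stv_factor = pos_stv_factor,
            pos_decel_factor = pos_decel_factor)
  rates <- c(accel_rate, decel_rate, artifact_rate)
  if (any(rates < 0)) stop("event rates must be >= 0")
  if (baseline_mean <= 50 || baseline_mean >= 230)
    stop("baseline_mean must lie in (50, 230) bpm")
  if (dropout_enter_prob < 0 || dropout_enter_prob > 1 ||
      dropout_exit_prob < 0 || dropout_exit_prob > 1)
    stop("dropout probabilities must lie in [0, 1]")
  if (stv_target < 0) stop("stv_target must be >= 0")
  if (duration < 1) stop("duration must be at least 1 minute")
  class(p) <- "SimParams"
  p
}

# run RNG-dependent code under `seed` without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# alternating geometric run lengths == two-state Markov chain occupancy
simulateDropoutMask <- function(n, p_enter, p_exit) {
  if (p_enter <= 0) return(rep(TRUE, n))
  if (p_exit <= 0) stop("dropout_exit_prob must be > 0 when dropout can occur")
  # expected runs: n / (mean valid run + mean gap run), padded generously
  n_runs <- max(16L, ceiling(2.5 * n * (1 / (1 / p_enter + 1 / p_exit))) + 8L)
  repeat {
    valid_runs <- stats::rgeom(n_runs, p_enter) + 1L
    gap_runs   <- stats::rgeom(n_runs, p_exit) + 1L
    total <- sum(valid_runs) + sum(gap_runs)
    if (total >= n + 1L) break
    n_runs <- n_runs * 2L
  }
  lens <- as.vector(rbind(valid_runs, gap_runs))
  states <- rep(rep(c(TRUE, FALSE), n_runs), lens)
  # random phase start from the stationary distribution
  start <- if (stats::runif(1) < p_exit / (p_enter + p_exit)) {
    1L
  } else {
    valid_runs[1L] + 1L
  }
  states[seq.int(start, length.out = n)]
}

# smooth unimodal bump (Hann shape) added in place
addBump <- function(x, start, len, amp) {
  n <- length(x)
  idx <- seq.int(start, min(n, start + len - 1L))   # truncated at the edge
  shape <- 0.5 * (1 - cos(2 * pi * (seq.int(0, len - 1)) / (len - 1)))
  x[idx] <- x[idx] + amp * shape[seq_along(idx)]
  x
}

#' Simulate one synthetic FHR record
#'
#' Generates a 4 Hz fetal heart rate trace with the statistical structure
#' the classification pipeline assumes: a bounded slowly drifting baseline,
#' calibrated short-term variability, smooth accelerations and
#' decelerations, two-state Markov sensor dropout (encoded in the validity
#' mask), and injected artifacts (spikes above 230 bpm, drops below 50 bpm,
#' and contiguous maternal-heart-rate capture episodes at about half the
#' fetal rate). A positive outcome lowers the STV target and raises the
#' deceleration rate by the configured effect sizes.
#'
#' @param params a \code{\link{simParams}} object.
#' @param outcome 0 (no compromise) or 1 (severe compromise).
#' @param record_id identifier for the returned record.
#' @return An \linkS4class{FHRRecord} at 4 Hz.
#' @examples
#' rec <- simulateRecord(simParams(duration = 20, seed = 7), outcome = 1)
#' rec
#' @export
simulateRecord <- function(params, outcome = 0, record_id = "sim") {
  stopifnot(inherits(params, "SimParams"))
  if (!outcome %in% c(0, 1)) stop("outcome must be 0 or 1")
  if (params$duration < 1) stop("duration must be at least 1 minute")

  stv_t  <- params$stv_target * if (outcome == 1) params$pos_stv_factor else 1
  dec_r  <- params$decel_rate * if (outcome == 1) params$pos_decel_factor else 1

  rate <- 4
  n <- round(params$duration * 60 * rate)
  ep_len <- 15L                       # 3.75 s epochs at 4 Hz
  n_ep <- ceiling(n / ep_len)
  hours <- params$duration / 60

  withSeed(params$seed, {
    # slow baseline: per-epoch AR(1) with stationary sd = baseline_sd
    phi <- 0.999
    innov_sd <- params$baseline_sd * sqrt(1 - phi^2)
    b <- numeric(n_ep)
    b[1] <- params$baseline_mean + stats::rnorm(1, 0, params$baseline_sd)
    e <- stats::rnorm(n_ep, 0, innov_sd)
    for (k in 2:n_ep)
      b[k] <- params$baseline_mean + phi * (b[k - 1] - params$baseline_mean) + e[k]
    b <- pmin(pmax(b, 90), 200)

    # beat-interval jitter calibrated against mean |successive difference|,
    # net of the baseline walk's own epoch-to-epoch interval change
    drift_sd <- (60000 / params$baseline_mean^2) * innov_sd
    jit_var <- max(stv_t^2 * pi / 4 - drift_sd^2 / 2, 0)
    jit <- stats::rnorm(n_ep, 0, sqrt(jit_var))
    interval <- 60000 / b + jit                       # ms per beat, per epoch
    bpm_ep <- 60000 / pmax(interval, 60000 / 250)

    x <- rep(bpm_ep, each = ep_len)[seq_len(n)]
    x <- x + stats::rnorm(n, 0, 0.25)                 # within-epoch texture

    # accelerations and decelerations: smooth 1-3 min bumps
    n_acc <- stats::rpois(1, params$accel_rate * hours)
    n_dec <- stats::rpois(1, dec_r * hours)
    for (i in seq_len(n_acc)) {
      len <- round(stats::runif(1, 1, 3) * 60 * rate)
      start <- sample.int(max(n - 10L, 1L), 1)
      x <- addBump(x, start, len, 15)
    }
    for (i in seq_len(n_dec)) {
      len <- round(stats::runif(1, 1, 3) * 60 * rate)
      start <- sample.int(max(n - 10L, 1L), 1)
      x <- addBump(x, start, len, -params$decel_depth)
    }
    x <- pmin(pmax(x, 1), 299)        # valid physiological support pre-artifact

    # artifact episodes; values change but the mask stays TRUE -- the
    # cleaning stage is what is expected to catch the out-of-range ones
    n_art <- stats::rpois(1, params$artifact_rate * hours)
    for (i in seq_len(n_art)) {
      kind <- sample(c("spike_high", "spike_low", "mhr"), 1)
      if (kind == "spike_high") {
        len <- sample(3:6, 1)
        start <- sample.int(max(n - len, 1L), 1)
        x[start:(start + len - 1L)] <- stats::runif(len, 231, 255)
      } else if (kind == "spike_low") {
        len <- sample(3:6, 1)
        start <- sample.int(max(n - len, 1L), 1)
        x[start:(start + len - 1L)] <- stats::runif(len, 25, 49)
      } else {
        len <- round(stats::runif(1, 30, 90) * rate)
        start <- sample.int(max(n - len, 1L), 1)
        idx <- start:min(n, start + len - 1L)
        x[idx] <- 0.5 * x[idx] + stats::rnorm(length(idx), 0, 1)
      }
    }

    mask <- simulateDropoutMask(n, params$dropout_enter_prob,
                                params$dropout_exit_prob)
    FHRRecord(x, validMask = mask, rate = rate, outcome = outcome,
              recordId = record_id)
  })
}

#' Simulate a cohort of FHR records with a fixed prevalence
#'
#' Draws exactly \code{round(n_records * prevalence)} positive records and
#' the rest negative, simulating each record with a per-record seed derived
#' deterministically from \code{seed}. If \code{dir} is given, each record
#' is written as a two-column CSV with a JSON sidecar and a manifest TSV
#' (\code{record_id}, \code{path}, \code{outcome}) is written alongside.
#'
#' @param n_records number of records (>= 2).
#' @param prevalence positive-class fraction in (0, 1).
#' @param params baseline \code{\link{simParams}} shared by both classes;
#'   class effects then come from the params' own effect-size fields.
#' @param params_by_class optional list with elements \code{negative} and
#'   \code{positive}, overriding \code{params} per class (the effect-size
#'   fields of the class-specific params still apply on top).
#' @param seed master integer seed.
#' @param dir optional directory for record files and the manifest.
#' @return A \code{data.frame} manifest (record_id, path, outcome) with
#'   attributes \code{prevalence} and \code{seed}; \code{path} is \code{NA}
#'   when nothing is written.
#' @examples
#' man <- simulateCohort(20, 0.5, simParams(duration = 20), seed = 1)
#' table(man$outcome)
#' @export
simulateCohort <- function(n_records, prevalence, params = simParams(),
                           params_by_class = NULL, seed = 1L, dir = NULL) {
  if (n_records < 2) stop("n_records must be >= 2")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly in (0, 1)")
  n_pos <- round(n_records * prevalence)
  if (n_pos < 1)
    stop(sprintf(
      "prevalence %.4g yields 0 positives; need n_records >= %d",
      prevalence, ceiling(0.5 / prevalence)))
  outcomes <- c(rep(1L, n_pos), rep(0L, n_records - n_pos))

  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n_records))
  ids <- sprintf("rec%04d", seq_len(n_records))

  paths <- rep(NA_character_, n_records)
  records <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    p <- if (!is.null(params_by_class)) {
      if (outcomes[i] == 1) params_by_class$positive else params_by_class$negative
    } else params
    p$seed <- seeds[i]
    rec <- simulateRecord(p, outcome = outcomes[i], record_id = ids[i])
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths[i] <- file.path(dir, paste0(ids[i], ".csv"))
      writeRecord(rec, paths[i])
    } else {
      records[[i]] <- rec
    }
  }

  manifest <- data.frame(record_id = ids, path = paths, outcome = outcomes,
                         stringsAsFactors = FALSE)
  attr(manifest, "prevalence") <- n_pos / n_records
  attr(manifest, "seed") <- as.integer(seed)
  if (is.null(dir)) attr(manifest, "records") <- records
  if (!is.null(dir))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  manifest
}

#' Fetch the in-memory records attached to a manifest
#'
#' @param manifest result of \code{\link{simulateCohort}}.
#' @return list of \linkS4class{FHRRecord}s, loaded from disk when the
#'   cohort was written to files.
#' @export
cohortRecords <- function(manifest) {
  recs <- attr(manifest, "records")
  if (!is.null(recs)) return(recs)
  lapply(manifest$path, readRecord)
}
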