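#' Training configuration
#'
#' The training protocol: 85/15 stratified record-level split, 10-fold
#' cross-validation on the training set, weighted binary cross-entropy,
#' Adam starting at 0.001 and halved every 50 epochs, batch size 128, at
#' most 400 epochs with early stopping on validation partial AUC over a
#' 50-epoch window.
#'
#' @param split training fraction of the record-level split.
#' @param folds number of cross-validation folds.
#' @param max_epochs maximum training epochs.
#' @param early_stop_window epochs without validation-PAUC improvement
#'   before stopping.
#' @param lr0 initial Adam learning rate.
#' @param lr_decay_every epochs between decays.
#' @param lr_decay_factor division factor per decay.
#' @param batch_size minibatch size (128 per the protocol; 512 is the
#'   tuned alternative).
#' @param pos_weight positive-class loss weight; \code{NULL} = inverse
#'   class frequency of the training data.
#' @param seed master seed; per-fold seeds are fanned out
#'   deterministically.
#' @return List of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(split = 0.85, folds = 10, max_epochs = 400,
                        early_stop_window = 50, lr0 = 0.001,
                        lr_decay_every = 50, lr_decay_factor = 2,
                        batch_size = 128, pos_weight = NULL, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  structure(list(split = split, folds = as.integer(folds),
                 max_epochs = as.integer(max_epochs),
                 early_stop_window = as.integer(early_stop_window),
                 lr0 = lr0, lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 batch_size = as.integer(batch_size),
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Learning rate at a given epoch under the step-decay schedule
#'
#' @param epoch 1-based epoch number.
#' @param cfg a \code{\link{trainConfig}}.
#' @return learning rate (\code{lr0 / factor^floor(epoch / every)}; epoch
#'   100 with the defaults gives \code{lr0 / 4}).
#' @export
learningRate <- function(epoch, cfg = trainConfig()) {
  cfg$lr0 / cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

#' Stratified record-level train/test split
#'
#' Records (not segments) are partitioned 85/15 preserving the class
#' ratio within rounding, so augmented windows of one record can never
#' straddle the split.
#'
#' @param manifest cohort manifest with \code{record_id} and
#'   \code{outcome} columns.
#' @param split training fraction.
#' @param seed integer seed (same seed, same partition).
#' @return List with character vectors \code{train_ids}, \code{test_ids}.
#' @export
splitCohort <- function(manifest, split = 0.85, seed = 1L) {
  for (cls in c(0, 1))
    if (sum(manifest$outcome == cls) < 2)
      stop("each class needs at least 2 records to split")
  withSeed(seed, {
    train_ids <- character(0)
    for (cls in c(0, 1)) {
      ids <- manifest$record_id[manifest$outcome == cls]
      n_tr <- round(split * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
      train_ids <- c(train_ids, sample(ids, n_tr))
    }
    list(train_ids = sort(train_ids),
         test_ids = sort(setdiff(manifest$record_id, train_ids)))
  })
}

#' Grouped stratified fold assignment
#'
#' Assigns records to folds so that all segments of a record share a fold
#' and each fold holds positives (stratified round-robin after a seeded
#' shuffle).
#'
#' @param record_ids unique record identifiers.
#' @param outcomes 0/1 outcome per record.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return named integer vector: fold of each record.
#' @export
foldAssign <- function(record_ids, outcomes, folds = 10, seed = 1L) {
  if (sum(outcomes == 1) < folds)
    stop(sprintf(paste0("only %d positive records for %d folds; every fold ",
                        "needs a positive (use grouped stratified folds ",
                        "with fewer folds or more data)"),
                 sum(outcomes == 1), folds))
  withSeed(seed, {
    fold <- integer(length(record_ids))
    names(fold) <- record_ids
    for (cls in c(1, 0)) {
      ids <- record_ids[outcomes == cls]
      ids <- sample(ids)
      fold[ids] <- rep_len(seq_len(folds), length(ids))
    }
    fold
  })
}

sliceInputs <- function(inputs, idx) {
  sl <- function(x) {
    d <- dim(x)
    if (length(d) == 3L) x[idx, , , drop = FALSE]
    else x[idx, , , , drop = FALSE]
  }
  if (is.list(inputs)) lapply(inputs, sl) else sl(inputs)
}

nSamples <- function(inputs) {
  if (is.list(inputs)) dim(inputs[[1]])[1] else dim(inputs)[1]
}

#' Train a model with weighted BCE, Adam and early stopping
#'
#' Minibatch training under the step-decay Adam schedule, monitoring the
#' standardized partial AUC on the validation set; training stops when
#' the validation PAUC has not improved for \code{early_stop_window}
#' epochs and the best-epoch weights are restored, so the returned model
#' is never worse (on validation PAUC) than any intermediate epoch.
#'
#' @param model a built \code{ctgModel}.
#' @param inputs training inputs (array or \code{list(signal=, image=)}).
#' @param labels 0/1 training labels.
#' @param cfg a \code{\link{trainConfig}}.
#' @param val_inputs,val_labels validation set for early stopping;
#'   \code{NULL} disables it (training runs all epochs).
#' @param pos_weight positive-class weight; default from
#'   \code{\link{classWeight}} on the training labels.
#' @param verbose print per-epoch progress.
#' @return The model with trained weights and a \code{history} element
#'   (per-epoch loss, validation PAUC, learning rate, best epoch).
#' @export
trainModel <- function(model, inputs, labels, cfg = trainConfig(),
                       val_inputs = NULL, val_labels = NULL,
                       pos_weight = NULL, verbose = FALSE) {
  n <- nSamples(inputs)
  stopifnot(length(labels) == n)
  if (is.null(pos_weight)) {
    pos_weight <- cfg$pos_weight
    if (is.null(pos_weight)) {
      n_pos <- sum(labels == 1)
      pos_weight <- if (n_pos > 0 && n_pos < n)
        as.numeric(classWeight(n - n_pos, n_pos)) else 1
    }
  }

  params <- getParams(model)
  adam <- adamInit(params)
  step <- 0L
  best <- list(pauc = -Inf, epoch = 0L, params = params,
               bn = bnSnapshot(model))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_pauc = numeric(0), lr = numeric(0))

  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- learningRate(epoch, cfg)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (bstart in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- ord[bstart:min(n, bstart + cfg$batch_size - 1L)]
        xb <- sliceInputs(inputs, idx)
        yb <- labels[idx]
        fw <- modelForward(model, xb, training = TRUE)
        losses <- c(losses, weightedBCE(fw$p, yb, pos_weight))
        dlogit <- matrix(bceLogitGrad(fw$p, yb, pos_weight), ncol = 1)
        grads <- modelBackward(model, fw$caches, dlogit)
        step <- step + 1L
        upd <- adamStep(params, grads, adam, lr, step)
        params <- upd$params
        adam <- upd$state
        model <- setParams(model, params)
      }
      val_pauc <- NA_real_
      if (!is.null(val_inputs)) {
        vp <- predictProb(model, val_inputs)
        val_pauc <- pauc(val_labels, vp, 0.1)
        if (val_pauc > best$pauc) {
          best <- list(pauc = val_pauc, epoch = epoch, params = params,
                       bn = bnSnapshot(model))
        }
        if (epoch - best$epoch >= cfg$early_stop_window) {
          if (verbose)
            message(sprintf("early stop at epoch %d (best %d)", epoch,
                            best$epoch))
          history <- rbind(history, data.frame(
            epoch = epoch, loss = mean(losses), val_pauc = val_pauc, lr = lr))
          break
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = mean(losses), val_pauc = val_pauc, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d loss %.4f val_pauc %s lr %.2g", epoch,
                        mean(losses),
                        ifelse(is.na(val_pauc), "-", sprintf("%.3f", val_pauc)),
                        lr))
    }
  })

  if (!is.null(val_inputs) && best$epoch > 0L) {
    model <- setParams(model, best$params)
    bnRestore(model, best$bn)
  }
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_pauc <- best$pauc
  model$pos_weight <- pos_weight
  model
}

#' Grouped 10-fold cross-validation with test-set evaluation
#'
#' For each fold: the fold's records form the validation set, the rest of
#' the training records the training set; the model trains with weighted
#' BCE, the Adam schedule and early stopping on validation PAUC, and is
#' then evaluated on the untouched test set. Augmented windows of one
#' record always share a fold.
#'
#' @param train_data,test_data lists with elements \code{inputs} (array
#'   or \code{list(signal=, image=)}), \code{labels} and \code{groups}
#'   (record id per sample).
#' @param spec a \code{\link{modelSpec}}.
#' @param cfg a \code{\link{trainConfig}}.
#' @param keep_models return the trained models (memory permitting).
#' @return List of class \code{"CVResult"}: \code{reports} (per-fold
#'   \code{\link{evalReport}}s on the test set), \code{mean} (averaged
#'   metrics), \code{fold_of_record}, and optionally \code{models}.
#' @export
crossValidate <- function(train_data, test_data, spec, cfg = trainConfig(),
                          keep_models = FALSE) {
  groups <- train_data$groups
  rec_ids <- unique(groups)
  rec_out <- vapply(rec_ids,
                    function(id) max(train_data$labels[groups == id]), 0)
  fold <- foldAssign(rec_ids, rec_out, cfg$folds, cfg$seed)
  fold_seeds <- withSeed(cfg$seed,
                         sample.int(.Machine$integer.max - 1L, cfg$folds))

  reports <- vector("list", cfg$folds)
  models <- if (keep_models) vector("list", cfg$folds) else NULL
  score_mat <- matrix(NA_real_, cfg$folds, length(test_data$labels))
  for (f in seq_len(cfg$folds)) {
    val_ids <- rec_ids[fold[rec_ids] == f]
    tr_idx <- which(!groups %in% val_ids)
    va_idx <- which(groups %in% val_ids)
    fold_cfg <- cfg
    fold_cfg$seed <- fold_seeds[f]
    model <- buildModel(spec, seed = fold_seeds[f])
    model <- trainModel(model, sliceInputs(train_data$inputs, tr_idx),
                        train_data$labels[tr_idx], fold_cfg,
                        val_inputs = sliceInputs(train_data$inputs, va_idx),
                        val_labels = train_data$labels[va_idx])
    scores <- predictProb(model, test_data$inputs)
    score_mat[f, ] <- scores
    reports[[f]] <- evalReport(test_data$labels, scores)
    if (keep_models) models[[f]] <- model
  }

  metric_names <- c("pauc_std", "sens_at_95spec", "auc", "precision",
                    "recall", "f1")
  mean_metrics <- vapply(metric_names, function(mn)
    mean(vapply(reports, function(r) r[[mn]], 0)), 0)
  structure(list(reports = reports, mean = as.list(mean_metrics),
                 fold_of_record = fold, test_scores = score_mat,
                 models = models),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf(paste0("CVResult over %d folds (test-set means): PAUC %.3f | ",
                     "TPR@95%% spec %.3f | AUC %.3f\n"),
              length(x$reports), x$mean$pauc_std, x$mean$sens_at_95spec,
              x$mean$auc))
  invisible(x)
}
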