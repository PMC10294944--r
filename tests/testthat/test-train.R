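test_that("the stratified record split preserves counts and is reproducible", {
  man <- data.frame(record_id = sprintf("r%03d", 1:1000),
                    outcome = c(rep(1L, 9), rep(0L, 991)))
  sp <- splitCohort(man, 0.85, seed = 3)
  expect_length(sp$test_ids, 150)
  n_pos_test <- sum(man$outcome[man$record_id %in% sp$test_ids])
  expect_true(n_pos_test %in% c(1, 2))
  expect_identical(sp, splitCohort(man, 0.85, seed = 3))
  expect_false(identical(sp, splitCohort(man, 0.85, seed = 4)))
  expect_error(splitCohort(data.frame(record_id = "a", outcome = 1L)),
               "at least 2")
})

test_that("grouped folds keep records together and every fold holds positives", {
  ids <- sprintf("r%02d", 1:40)
  out <- c(rep(1, 12), rep(0, 28))
  fold <- foldAssign(ids, out, folds = 10, seed = 1)
  expect_setequal(names(fold), ids)
  pos_per_fold <- table(fold[ids[out == 1]])
  expect_true(all(pos_per_fold >= 1))
  expect_length(unique(fold), 10)
  expect_error(foldAssign(ids, c(rep(1, 5), rep(0, 35)), folds = 10),
               "grouped stratified")
})

test_that("augmented windows of one record never straddle split or folds", {
  man <- data.frame(record_id = sprintf("r%02d", 1:30),
                    outcome = rep(c(1L, 0L, 0L), 10))
  sp <- splitCohort(man, 0.85, seed = 5)
  # segment-level provenance: 4 windows per positive record
  segs <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
    k <- if (man$outcome[i] == 1) 4 else 1
    data.frame(record_id = man$record_id[i], window = seq_len(k))
  }))
  in_train <- segs$record_id %in% sp$train_ids
  straddle <- tapply(in_train, segs$record_id, function(v) length(unique(v)))
  expect_true(all(straddle == 1))
})

test_that("the learning-rate schedule halves every 50 epochs", {
  cfg <- trainConfig()
  expect_equal(learningRate(100, cfg), cfg$lr0 / 4)
  expect_equal(learningRate(1, cfg), cfg$lr0)
  expect_equal(learningRate(49, cfg), cfg$lr0)
  expect_equal(learningRate(150, cfg), cfg$lr0 / 8)
})

test_that("training is deterministic given the seed and records history", {
  set.seed(50)
  n <- 24
  y <- rep(c(0, 1), n / 2)
  X <- array(rnorm(n * 300) + rep(y, 300), c(n, 300, 1))
  cfg <- trainConfig(max_epochs = 3, batch_size = 8, seed = 9)
  m1 <- trainModel(buildModel(modelSpec("cnn1d", dropout = 0), seed = 2),
                   X, y, cfg)
  m2 <- trainModel(buildModel(modelSpec("cnn1d", dropout = 0), seed = 2),
                   X, y, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(predictProb(m1, X), predictProb(m2, X))
  expect_equal(nrow(m1$history), 3)
})

test_that("early stopping restores the best-validation-PAUC weights", {
  set.seed(51)
  n <- 40
  y <- rep(c(0, 1), n / 2)
  X <- array(rnorm(n * 300) + rep(y, 300) * 0.6, c(n, 300, 1))
  vi <- c(1:6, 35:40)                 # both classes present in validation
  cfg <- trainConfig(max_epochs = 25, early_stop_window = 5,
                     batch_size = 20, lr0 = 0.003, seed = 10)
  m <- trainModel(buildModel(modelSpec("cnn1d", dropout = 0), seed = 3),
                  X[-vi, , , drop = FALSE], y[-vi], cfg,
                  val_inputs = X[vi, , , drop = FALSE], val_labels = y[vi])
  expect_true(m$best_epoch >= 1)
  # the restored model reproduces the recorded best validation PAUC
  vp <- pauc(y[vi], predictProb(m, X[vi, , , drop = FALSE]), 0.1)
  expect_equal(vp, m$best_val_pauc)
  expect_equal(m$best_val_pauc, max(m$history$val_pauc, na.rm = TRUE))
})

test_that("cross-validation reports per-fold test metrics with grouped folds", {
  set.seed(52)
  n_rec <- 40
  y_rec <- rep(c(1, 0, 0, 0), 10)
  X <- array(rnorm(n_rec * 300) + rep(y_rec, 300) * 0.8, c(n_rec, 300, 1))
  train_data <- list(inputs = X[1:32, , , drop = FALSE], labels = y_rec[1:32],
                     groups = sprintf("r%02d", 1:32))
  test_data <- list(inputs = X[33:40, , , drop = FALSE],
                    labels = y_rec[33:40],
                    groups = sprintf("r%02d", 33:40))
  cfg <- trainConfig(folds = 4, max_epochs = 4, batch_size = 16,
                     lr0 = 0.003, seed = 11)
  cv <- crossValidate(train_data, test_data, modelSpec("cnn1d", dropout = 0),
                      cfg)
  expect_length(cv$reports, 4)
  expect_true(all(vapply(cv$reports, function(r) r$pauc_std, 0) >= 0))
  expect_equal(dim(cv$test_scores), c(4L, 8L))
  expect_true(all(is.finite(cv$test_scores)))
  expect_equal(cv$mean$pauc_std,
               mean(vapply(cv$reports, function(r) r$pauc_std, 0)))
})
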