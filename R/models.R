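#' Model specification for the five network architectures
#'
#' The tuned defaults: five 1D convolutional layers with filter counts
#' (16, 32, 64, 64, 16) and kernel 3, two LSTM layers of 16 units, two
#' fully connected layers, dropout 0.3 in all layers, 3 x 3 kernels and
#' five residual blocks for the 2D network.
#'
#' @param arch one of \code{"cnn1d"} (five 1D-CNN layers + 2 FC),
#'   \code{"cnn_lstm_seq"} (1D-CNN stack followed by 2 LSTM layers + 2 FC),
#'   \code{"cnn_lstm_par"} (1D-CNN stack and 2-layer LSTM in parallel on
#'   the raw signal, concatenated, + 2 FC), \code{"cnn2d_residual"}
#'   (2D-CNN with five residual blocks and average pooling on 128 x 128
#'   time-frequency images), \code{"multimodal"} (the parallel 1D branch
#'   and the residual 2D branch fed simultaneously, outputs concatenated
#'   into the FC head).
#' @param n_cnn_layers,kernel_size_1d,filters 1D convolution stack.
#' @param lstm_units,n_lstm_layers LSTM component.
#' @param fc_layers number of fully connected layers in the head (hidden
#'   width 64, final width 1).
#' @param dropout dropout probability in [0, 1).
#' @param kernel_size_2d 2D kernel size (3, 5 or 7).
#' @param n_residual_blocks residual blocks in the 2D network.
#' @return List of class \code{"ModelSpec"}.
#' @export
modelSpec <- function(arch = c("cnn1d", "cnn_lstm_seq", "cnn_lstm_par",
                               "cnn2d_residual", "multimodal"),
                      n_cnn_layers = 5, kernel_size_1d = 3,
                      filters = c(16, 32, 64, 64, 16),
                      lstm_units = 16, n_lstm_layers = 2, fc_layers = 2,
                      dropout = 0.3, kernel_size_2d = 3,
                      n_residual_blocks = 5) {
  arch <- match.arg(arch)
  if (length(filters) != n_cnn_layers)
    stop("filters must have length n_cnn_layers")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (fc_layers < 1) stop("fc_layers must be >= 1")
  structure(list(arch = arch, n_cnn_layers = as.integer(n_cnn_layers),
                 kernel_size_1d = as.integer(kernel_size_1d),
                 filters = as.integer(filters),
                 lstm_units = as.integer(lstm_units),
                 n_lstm_layers = as.integer(n_lstm_layers),
                 fc_layers = as.integer(fc_layers), dropout = dropout,
                 kernel_size_2d = as.integer(kernel_size_2d),
                 n_residual_blocks = as.integer(n_residual_blocks)),
            class = "ModelSpec")
}

#' Input shapes expected at model entry
#'
#' @param spec a \code{\link{modelSpec}}.
#' @return List with \code{signal} (T = 300, F = 1) and/or \code{image}
#'   (H = 128, W = 128, C = 3) entries, as the architecture requires.
#' @export
inputSpec <- function(spec) {
  sig <- c(T = 300L, F = 1L)
  img <- c(H = 128L, W = 128L, C = 3L)
  switch(spec$arch,
         cnn1d = , cnn_lstm_seq = , cnn_lstm_par = list(signal = sig),
         cnn2d_residual = list(image = img),
         multimodal = list(signal = sig, image = img))
}

buildConvStack1d <- function(spec, prefix, cin = 1L) {
  layers <- list()
  t_len <- 300L
  for (i in seq_len(spec$n_cnn_layers)) {
    cout <- spec$filters[i]
    layers <- c(layers, list(
      layerConv1d(sprintf("%s.conv%d", prefix, i), spec$kernel_size_1d, cin, cout),
      layerRelu(sprintf("%s.relu%d", prefix, i)),
      layerMaxPool1d(sprintf("%s.pool%d", prefix, i)),
      layerDropout(sprintf("%s.drop%d", prefix, i), spec$dropout)))
    cin <- cout
    t_len <- t_len %/% 2L
  }
  attr(layers, "t_out") <- t_len
  attr(layers, "c_out") <- cin
  layers
}

buildHead <- function(spec, n_in, prefix = "head") {
  layers <- list()
  w <- n_in
  for (i in seq_len(spec$fc_layers - 1L)) {
    layers <- c(layers, list(
      layerDense(sprintf("%s.fc%d", prefix, i), w, 64L),
      layerRelu(sprintf("%s.relu%d", prefix, i)),
      layerDropout(sprintf("%s.drop%d", prefix, i), spec$dropout)))
    w <- 64L
  }
  c(layers, list(layerDense(sprintf("%s.fc%d", prefix, spec$fc_layers), w, 1L)))
}

buildLSTMStack <- function(spec, prefix, cin) {
  layers <- list()
  for (i in seq_len(spec$n_lstm_layers)) {
    layers <- c(layers, list(layerLSTM(
      sprintf("%s.lstm%d", prefix, i), cin, spec$lstm_units,
      return_seq = i < spec$n_lstm_layers)))
    cin <- spec$lstm_units
  }
  layers
}

makeResBlock <- function(name, k, cin, cout, dropout) {
  list(type = "resblock", name = name,
       main = list(layerConv2d(paste0(name, ".conv"), k, cin, cout),
                   layerBatchNorm(paste0(name, ".bn"), cout),
                   layerRelu(paste0(name, ".relu")),
                   layerDropout(paste0(name, ".drop"), dropout),
                   layerMaxPool2d(paste0(name, ".pool"))),
       skip = list(layerConv2d(paste0(name, ".proj"), 1L, cin, cout),
                   layerMaxPool2d(paste0(name, ".skippool"))))
}

buildImageTrunk <- function(spec, prefix = "img") {
  # stride-2 stem keeps the residual stack tractable: 128 -> 64 into block 1
  stem <- list(layerConv2d(paste0(prefix, ".stem"), spec$kernel_size_2d, 3L,
                           spec$filters[1], stride = 2L),
               layerRelu(paste0(prefix, ".stemrelu")))
  chans <- rep_len(spec$filters, spec$n_residual_blocks)
  cin <- spec$filters[1]
  blocks <- list()
  for (i in seq_len(spec$n_residual_blocks)) {
    blocks[[i]] <- makeResBlock(sprintf("%s.block%d", prefix, i),
                                spec$kernel_size_2d, cin, chans[i],
                                spec$dropout)
    cin <- chans[i]
  }
  trunk <- c(stem, blocks, list(layerGlobalAvgPool2d(paste0(prefix, ".gap"))))
  attr(trunk, "c_out") <- cin
  trunk
}

#' Build a trainable model from a specification
#'
#' Constructs the architecture's layer graph with freshly initialised
#' weights (deterministic given \code{seed}). Hidden activations are ReLU;
#' the output is a single sigmoid probability per sample.
#'
#' @param spec a \code{\link{modelSpec}}.
#' @param seed integer seed for weight initialisation.
#' @return List of class \code{"ctgModel"}.
#' @examples
#' m <- buildModel(modelSpec("cnn1d"), seed = 1)
#' countLayers(m)
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  withSeed(seed, {
    modules <- switch(spec$arch,
      cnn1d = {
        trunk <- buildConvStack1d(spec, "trunk")
        flat <- attr(trunk, "t_out") * attr(trunk, "c_out")
        list(trunk = c(trunk, list(layerFlatten("trunk.flat"))),
             head = buildHead(spec, flat))
      },
      cnn_lstm_seq = {
        trunk <- buildConvStack1d(spec, "trunk")
        lstm <- buildLSTMStack(spec, "trunk", attr(trunk, "c_out"))
        list(trunk = c(trunk, lstm), head = buildHead(spec, spec$lstm_units))
      },
      cnn_lstm_par = {
        cnn <- buildConvStack1d(spec, "cnn")
        flat <- attr(cnn, "t_out") * attr(cnn, "c_out")
        lstm <- buildLSTMStack(spec, "lstm", 1L)
        list(cnn_branch = c(cnn, list(layerFlatten("cnn.flat"))),
             lstm_branch = lstm,
             head = buildHead(spec, flat + spec$lstm_units))
      },
      cnn2d_residual = {
        trunk <- buildImageTrunk(spec)
        list(trunk = trunk, head = buildHead(spec, attr(trunk, "c_out")))
      },
      multimodal = {
        cnn <- buildConvStack1d(spec, "cnn")
        flat <- attr(cnn, "t_out") * attr(cnn, "c_out")
        lstm <- buildLSTMStack(spec, "lstm", 1L)
        img <- buildImageTrunk(spec)
        list(cnn_branch = c(cnn, list(layerFlatten("cnn.flat"))),
             lstm_branch = lstm,
             img_trunk = img,
             head = buildHead(spec, flat + spec$lstm_units +
                                attr(img, "c_out")))
      })
    structure(list(arch = spec$arch, spec = spec, modules = modules),
              class = "ctgModel")
  })
}

# --- module-level forward/backward (handles resblock composites) ----------

moduleForward <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (identical(l$type, "resblock")) {
      rm <- moduleForward(l$main, X, training)
      rs <- moduleForward(l$skip, X, training)
      X <- rm$out + rs$out
      caches[[i]] <- list(main = rm$caches, skip = rs$caches)
    } else {
      r <- layerForward(l, X, training)
      X <- r$out
      caches[[i]] <- r$cache
    }
  }
  list(out = X, caches = caches)
}

moduleBackward <- function(layers, caches, dY) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (identical(l$type, "resblock")) {
      rm <- moduleBackward(l$main, caches[[i]]$main, dY)
      rs <- moduleBackward(l$skip, caches[[i]]$skip, dY)
      dY <- rm$din + rs$din
      grads <- c(grads, rm$grads, rs$grads)
    } else {
      r <- layerBackward(l, caches[[i]], dY)
      dY <- r$din
      if (length(r$grads)) grads[[l$name]] <- r$grads
    }
  }
  list(din = dY, grads = grads)
}

modelInputs <- function(model, inputs) {
  if (model$arch %in% c("cnn1d", "cnn_lstm_seq", "cnn_lstm_par")) {
    x <- if (is.list(inputs)) inputs$signal else inputs
    if (length(dim(x)) != 3L) stop("signal input must be a (B, T, F) array")
    list(signal = x)
  } else if (model$arch == "cnn2d_residual") {
    x <- if (is.list(inputs)) inputs$image else inputs
    if (length(dim(x)) != 4L) stop("image input must be a (B, H, W, C) array")
    list(image = x)
  } else {
    if (!is.list(inputs) || is.null(inputs$signal) || is.null(inputs$image))
      stop("multimodal input must be list(signal = , image = )")
    inputs
  }
}

modelForward <- function(model, inputs, training = FALSE) {
  inp <- modelInputs(model, inputs)
  m <- model$modules
  caches <- list()
  feat <- switch(model$arch,
    cnn1d = , cnn_lstm_seq = {
      r <- moduleForward(m$trunk, inp$signal, training)
      caches$trunk <- r$caches
      r$out
    },
    cnn_lstm_par = {
      rc <- moduleForward(m$cnn_branch, inp$signal, training)
      rl <- moduleForward(m$lstm_branch, inp$signal, training)
      caches$cnn_branch <- rc$caches; caches$lstm_branch <- rl$caches
      caches$split <- c(ncol(rc$out), ncol(rl$out))
      cbind(rc$out, rl$out)
    },
    cnn2d_residual = {
      r <- moduleForward(m$trunk, inp$image, training)
      caches$trunk <- r$caches
      r$out
    },
    multimodal = {
      rc <- moduleForward(m$cnn_branch, inp$signal, training)
      rl <- moduleForward(m$lstm_branch, inp$signal, training)
      ri <- moduleForward(m$img_trunk, inp$image, training)
      caches$cnn_branch <- rc$caches; caches$lstm_branch <- rl$caches
      caches$img_trunk <- ri$caches
      caches$split <- c(ncol(rc$out), ncol(rl$out), ncol(ri$out))
      cbind(rc$out, rl$out, ri$out)
    })
  rh <- moduleForward(m$head, feat, training)
  caches$head <- rh$caches
  logit <- rh$out
  list(p = as.vector(sigm(logit)), logit = logit, caches = caches)
}

modelBackward <- function(model, caches, dlogit) {
  m <- model$modules
  rh <- moduleBackward(m$head, caches$head, dlogit)
  grads <- rh$grads
  dfeat <- rh$din
  if (model$arch %in% c("cnn1d", "cnn_lstm_seq", "cnn2d_residual")) {
    rt <- moduleBackward(m$trunk, caches$trunk, dfeat)
    grads <- c(grads, rt$grads)
  } else if (model$arch == "cnn_lstm_par") {
    s <- caches$split
    rc <- moduleBackward(m$cnn_branch, caches$cnn_branch,
                         dfeat[, seq_len(s[1]), drop = FALSE])
    rl <- moduleBackward(m$lstm_branch, caches$lstm_branch,
                         dfeat[, s[1] + seq_len(s[2]), drop = FALSE])
    grads <- c(grads, rc$grads, rl$grads)
  } else {
    s <- caches$split
    rc <- moduleBackward(m$cnn_branch, caches$cnn_branch,
                         dfeat[, seq_len(s[1]), drop = FALSE])
    rl <- moduleBackward(m$lstm_branch, caches$lstm_branch,
                         dfeat[, s[1] + seq_len(s[2]), drop = FALSE])
    ri <- moduleBackward(m$img_trunk, caches$img_trunk,
                         dfeat[, s[1] + s[2] + seq_len(s[3]), drop = FALSE])
    grads <- c(grads, rc$grads, rl$grads, ri$grads)
  }
  grads
}

allLayers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (identical(l$type, "resblock")) {
      out <- c(out, allLayers(l$main), allLayers(l$skip))
    } else out[[l$name]] <- l
  }
  out
}

modelLayers <- function(model) {
  out <- list()
  for (mod in model$modules) out <- c(out, allLayers(mod))
  out
}

getParams <- function(model) {
  ls <- modelLayers(model)
  ps <- lapply(ls, function(l) l$params)
  ps[vapply(ps, length, 1L) > 0]
}

setParamsIn <- function(layers, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (identical(l$type, "resblock")) {
      layers[[i]]$main <- setParamsIn(l$main, params)
      layers[[i]]$skip <- setParamsIn(l$skip, params)
    } else if (!is.null(params[[l$name]])) {
      layers[[i]]$params <- params[[l$name]]
    }
  }
  layers
}

setParams <- function(model, params) {
  for (mn in names(model$modules))
    model$modules[[mn]] <- setParamsIn(model$modules[[mn]], params)
  model
}

bnSnapshot <- function(model) {
  ls <- modelLayers(model)
  out <- list()
  for (l in ls) if (identical(l$type, "batchnorm"))
    out[[l$name]] <- as.list(l$stateEnv)
  out
}

bnRestore <- function(model, snap) {
  ls <- modelLayers(model)
  for (l in ls) if (identical(l$type, "batchnorm") && !is.null(snap[[l$name]]))
    list2env(snap[[l$name]], l$stateEnv)
  invisible(model)
}

#' Predicted probabilities from a model
#'
#' Runs the network in inference mode (dropout off, batch norm on running
#' statistics).
#'
#' @param model a built (optionally trained) \code{ctgModel}.
#' @param inputs a (B, 300, 1) signal array, a (B, 128, 128, 3) image
#'   array, or \code{list(signal = , image = )} for the multimodal
#'   architecture.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(model, inputs) {
  modelForward(model, inputs, training = FALSE)$p
}

#' Architecture summary counts
#'
#' @param model a built \code{ctgModel}.
#' @return List with \code{n_conv} (1D/2D convolution layers outside
#'   residual blocks), \code{n_lstm}, \code{n_fc}, \code{n_residual}
#'   counts.
#' @export
countLayers <- function(model) {
  stopifnot(inherits(model, "ctgModel"))
  count_in <- function(layers, type) {
    n <- 0L
    for (l in layers) if (identical(l$type, type)) n <- n + 1L
    n
  }
  n_conv <- 0L; n_lstm <- 0L; n_fc <- 0L; n_res <- 0L
  for (mod in model$modules) {
    n_conv <- n_conv + count_in(mod, "conv1d") + count_in(mod, "conv2d")
    n_lstm <- n_lstm + count_in(mod, "lstm")
    n_fc <- n_fc + count_in(mod, "dense")
    n_res <- n_res + count_in(mod, "resblock")
  }
  list(n_conv = n_conv, n_lstm = n_lstm, n_fc = n_fc, n_residual = n_res)
}

#' @export
print.ctgModel <- function(x, ...) {
  cl <- countLayers(x)
  cat(sprintf("ctgModel '%s': %d conv, %d LSTM, %d FC, %d residual blocks\n",
              x$arch, cl$n_conv, cl$n_lstm, cl$n_fc, cl$n_residual))
  invisible(x)
}
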