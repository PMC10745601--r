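# Seeded training, validation and prediction loops: Adam on the mean
# squared error of predicted vs experimental pKd.

#' Training configuration
#'
#' Defaults follow the reference regime: 300 epochs, Adam with learning
#' rate 1e-4, batch size 128, MSE loss. The validation fraction (seeded
#' split, used for checkpoint selection) defaults to 0.1; set it to 0 to
#' train on everything.
#'
#' @param epochs number of epochs.
#' @param learningRate Adam step size.
#' @param batchSize minibatch size (the last incomplete batch is kept).
#' @param valFraction held-out fraction in [0, 1).
#' @param seed integer seed controlling initialization, shuffling, dropout
#'   and the validation split.
#' @param checkpointPolicy \code{"best_val"} (lowest validation loss) or
#'   \code{"last"}.
#' @param verbose print a line every \code{verbose} epochs (0 = quiet).
#' @return a \code{TrainConfig} object.
#' @export
trainConfig <- function(epochs = 300, learningRate = 1e-4, batchSize = 128,
                        valFraction = 0.1, seed = 1,
                        checkpointPolicy = "best_val", verbose = 0) {
  new("TrainConfig", epochs = as.numeric(epochs),
      learningRate = learningRate, batchSize = as.numeric(batchSize),
      valFraction = valFraction, seed = as.numeric(seed),
      checkpointPolicy = checkpointPolicy, verbose = as.numeric(verbose))
}

#' @exportClass TrainConfig
setClass("TrainConfig",
  slots = c(epochs = "numeric", learningRate = "numeric",
            batchSize = "numeric", valFraction = "numeric",
            seed = "numeric", checkpointPolicy = "character",
            verbose = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1) return("epochs must be >= 1")
  if (object@valFraction < 0 || object@valFraction >= 1)
    return("valFraction must lie in [0, 1)")
  if (!object@checkpointPolicy %in% c("best_val", "last"))
    return("checkpointPolicy must be best_val or last")
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1) return("batchSize must be >= 1")
  TRUE
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d epochs, Adam lr=%g, batch=%d, val=%.2f, seed=%d, checkpoint=%s\n",
    object@epochs, object@learningRate, object@batchSize,
    object@valFraction, object@seed, object@checkpointPolicy))
})

#' Seed every stochastic component
#'
#' All randomness in the package (weight initialization, shuffling, dropout,
#' synthetic data) is drawn from R's global generator; this seeds it and
#' records the seed so training histories can report it.
#'
#' @param seed integer seed.
#' @export
setGlobalSeed <- function(seed) {
  set.seed(seed)
  options(StructDTA.seed = seed)
  invisible(seed)
}

# Adam with bias correction; state is kept per parameter leaf, addressed by
# a flattened path through the nested parameter list.
.flattenLeaves <- function(x, prefix = character()) {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x))
      out <- c(out, .flattenLeaves(x[[nm]], c(prefix, nm)))
    out
  } else {
    setNames(list(x), paste(prefix, collapse = "."))
  }
}

.adamInit <- function(params) {
  leaves <- .flattenLeaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  pl <- .flattenLeaves(params)
  gl <- .flattenLeaves(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(gl)) {
    g <- gl[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    pl[[nm]] <- pl[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  # write leaves back into the nested structure
  params <- .unflattenInto(params, pl)
  list(params = params, state = state)
}

.unflattenInto <- function(params, leaves) {
  assign1 <- function(x, path, value) {
    if (length(path) == 1L) {
      x[[path]] <- value
    } else {
      x[[path[1]]] <- assign1(x[[path[1]]], path[-1], value)
    }
    x
  }
  for (nm in names(leaves))
    params <- assign1(params, strsplit(nm, ".", fixed = TRUE)[[1]],
                      leaves[[nm]])
  params
}

.evalLoss <- function(samples, params, config, batchSize = 256) {
  n <- length(samples)
  yhat <- numeric(n); y <- numeric(n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + batchSize - 1L, n)
    batch <- .prepareBatch(samples[idx], config)
    fw <- .modelForward(batch, params, config, training = FALSE)
    yhat[idx] <- fw$yhat; y[idx] <- batch$y
    i <- i + batchSize
  }
  list(loss = mean((yhat - y)^2), yhat = yhat, y = y)
}

#' Train the affinity model
#'
#' Minimizes the mean squared error between predicted and experimental pKd
#' with Adam. A seeded shuffle holds out \code{valFraction} of the samples
#' for validation and checkpoint selection; training loss, validation loss
#' and validation RMSE/PCC are recorded per epoch. A non-finite loss aborts
#' with a diagnostic naming the batch.
#'
#' @param samples list of featurized \linkS4class{ComplexSample}.
#' @param config a \code{ModelConfig}.
#' @param train a \code{TrainConfig}.
#' @return list with \code{params} (checkpoint per policy), \code{history}
#'   data.frame, \code{bestEpoch}, \code{config}, \code{train} and
#'   \code{seed}.
#' @export
trainModel <- function(samples, config = modelConfig(),
                       train = trainConfig()) {
  if (!length(samples)) stop("dataset is empty")
  setGlobalSeed(train@seed)
  nVal <- floor(train@valFraction * length(samples))
  perm <- sample(length(samples))
  valIdx <- if (nVal > 0) perm[seq_len(nVal)] else integer()
  trIdx <- setdiff(perm, valIdx)
  trSamples <- samples[trIdx]
  valSamples <- samples[valIdx]
  params <- initModelParams(config)
  state <- .adamInit(params)
  nTr <- length(trSamples)
  bs <- min(train@batchSize, nTr)
  history <- vector("list", train@epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (ep in seq_len(train@epochs)) {
    ord <- sample(nTr)
    i <- 1L
    epLoss <- 0; bcount <- 0L
    while (i <= nTr) {
      idx <- ord[i:min(i + bs - 1L, nTr)]
      batch <- .prepareBatch(trSamples[idx], config)
      fw <- .modelForward(batch, params, config, training = TRUE)
      err <- fw$yhat - batch$y
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep, ", batch starting ",
             "at sample ", i, " (ids: ",
             paste(head(batch$ids, 5), collapse = ","), ")")
      grads <- .modelBackward(fw, batch, params, config,
                              dy = 2 * err / length(err))
      upd <- .adamStep(params, grads, state, train@learningRate)
      params <- upd$params; state <- upd$state
      epLoss <- epLoss + loss * length(idx); bcount <- bcount + length(idx)
      i <- i + bs
    }
    epLoss <- epLoss / bcount
    row <- data.frame(epoch = ep, train_loss = epLoss,
                      val_loss = NA_real_, val_rmse = NA_real_,
                      val_pcc = NA_real_)
    if (length(valSamples)) {
      ev <- .evalLoss(valSamples, params, config)
      row$val_loss <- ev$loss
      row$val_rmse <- sqrt(ev$loss)
      row$val_pcc <- if (length(ev$y) >= 2 && sd(ev$y) > 0 &&
                         sd(ev$yhat) > 0) cor(ev$y, ev$yhat) else NA_real_
      if (ev$loss < best$loss)
        best <- list(loss = ev$loss, params = params, epoch = ep)
    }
    history[[ep]] <- row
    if (train@verbose > 0 && ep %% train@verbose == 0)
      message(sprintf("epoch %d/%d  train MSE %.4f  val MSE %s", ep,
                      train@epochs, epLoss,
                      ifelse(is.na(row$val_loss), "-",
                             sprintf("%.4f", row$val_loss))))
  }
  history <- do.call(rbind, history)
  attr(history, "seed") <- train@seed
  usedBest <- train@checkpointPolicy == "best_val" && best$epoch > 0L
  list(params = if (usedBest) best$params else params,
       history = history,
       bestEpoch = if (usedBest) best$epoch else as.integer(train@epochs),
       config = config, train = train, seed = train@seed)
}

#' Predict affinities for featurized complexes
#'
#' Evaluation mode (dropout off), deterministic, order preserving.
#'
#' @param fit result of \code{\link{trainModel}}, or a parameter list (then
#'   pass \code{config}).
#' @param samples list of featurized \linkS4class{ComplexSample}.
#' @param config \code{ModelConfig}; taken from \code{fit} when present.
#' @param batchSize evaluation batch size.
#' @return data.frame with columns complex_id, y_true, y_pred in input
#'   order.
#' @export
predictAffinity <- function(fit, samples, config = NULL, batchSize = 256) {
  if (is.list(fit) && !is.null(fit$params)) {
    params <- fit$params
    if (is.null(config)) config <- fit$config
  } else params <- fit
  if (is.null(config)) stop("config required when fit is a bare parameter list")
  if (!length(samples)) stop("no samples to predict")
  ev <- .evalLoss(samples, params, config, batchSize)
  data.frame(complex_id = vapply(samples, function(s) s@id, character(1)),
             y_true = ev$y, y_pred = ev$yhat, stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint archive embeds the model configuration, training
#' configuration and seed alongside the parameters so a reload can verify
#' compatibility.
#'
#' @param fit result of \code{\link{trainModel}}.
#' @param path checkpoint path.
#' @export
saveCheckpoint <- function(fit, path) {
  stopifnot(!is.null(fit$params), !is.null(fit$config))
  saveRDS(list(params = fit$params, config = fit$config,
               train = fit$train, seed = fit$seed,
               bestEpoch = fit$bestEpoch,
               package_version = as.character(utils::packageVersion("StructDTA"))),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (is.null(ck$params) || is.null(ck$config))
    stop("invalid checkpoint: missing params or config in ", path)
  ck
}
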