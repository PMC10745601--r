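# The heterogeneous affinity model: per-stream sequence encoders (1D-CNN by
# default; LSTM, BiLSTM and CNN+LSTM variants), three independent 3-layer
# GNN stacks over the drug, target and pocket graphs, mean/max readout,
# per-stream linear projection to 256, and a two-layer fully connected head
# that maps the concatenated 768-vector to the predicted pKd.

#' Model configuration
#'
#' Defaults follow the reference architecture: one-hot inputs, target
#' convolution kernel 5 and pocket kernel 3 (stride 1, 128 output channels,
#' zero 'same' padding), GNN stack dimensions 32/64/128, per-stream linear
#' projection to 256, fully connected head 768 -> 256 -> 1 with LeakyReLU
#' and dropout 0.4, mean readout, LeakyReLU negative slope 0.01. Fixed
#' sequence lengths: 2100 (targets), 125 (pockets).
#'
#' @param seqEncoder one of \code{"CNN"}, \code{"LSTM"}, \code{"BiLSTM"},
#'   \code{"CNN_LSTM"}, \code{"none"} (one-hot fed straight to the GNN).
#' @param gnnLayer one of \code{"GraphSAGE"}, \code{"GCN"}, \code{"GAT"},
#'   \code{"GIN"}.
#' @param gnnDims three layer widths.
#' @param seqOutDim sequence-encoder output channels.
#' @param targetKernel,pocketKernel odd convolution kernel sizes.
#' @param projectionDim per-stream projection width.
#' @param fcHidden hidden width of the fusion head.
#' @param dropout dropout rate in the fusion head, in [0, 1).
#' @param pooling \code{"mean"} or \code{"max"} readout.
#' @param negativeSlope LeakyReLU negative slope.
#' @param contactCutoff residue-contact distance cutoff in Angstrom.
#' @param targetLength,pocketLength fixed sequence lengths for padding.
#' @param residueVocab,atomVocab encoding vocabularies.
#' @return a \code{ModelConfig} object.
#' @export
modelConfig <- function(seqEncoder = "CNN", gnnLayer = "GraphSAGE",
                        gnnDims = c(32, 64, 128), seqOutDim = 128,
                        targetKernel = 5, pocketKernel = 3,
                        projectionDim = 256, fcHidden = 256, dropout = 0.4,
                        pooling = "mean", negativeSlope = 0.01,
                        contactCutoff = 8.0,
                        targetLength = 2100, pocketLength = 125,
                        residueVocab = defaultResidueVocab(),
                        atomVocab = defaultAtomVocab()) {
  new("ModelConfig", seqEncoder = seqEncoder, gnnLayer = gnnLayer,
      gnnDims = as.numeric(gnnDims), seqOutDim = seqOutDim,
      targetKernel = targetKernel, pocketKernel = pocketKernel,
      projectionDim = projectionDim, fcHidden = fcHidden, dropout = dropout,
      pooling = pooling, negativeSlope = negativeSlope,
      contactCutoff = contactCutoff,
      targetLength = targetLength, pocketLength = pocketLength,
      residueVocab = residueVocab, atomVocab = atomVocab)
}

#' @exportClass ModelConfig
setClass("ModelConfig",
  slots = c(seqEncoder = "character", gnnLayer = "character",
            gnnDims = "numeric", seqOutDim = "numeric",
            targetKernel = "numeric", pocketKernel = "numeric",
            projectionDim = "numeric", fcHidden = "numeric",
            dropout = "numeric", pooling = "character",
            negativeSlope = "numeric", contactCutoff = "numeric",
            targetLength = "numeric", pocketLength = "numeric",
            residueVocab = "character", atomVocab = "character"))

setValidity("ModelConfig", function(object) {
  if (!object@seqEncoder %in% c("CNN", "LSTM", "BiLSTM", "CNN_LSTM", "none"))
    return("seqEncoder must be CNN, LSTM, BiLSTM, CNN_LSTM or none")
  if (!object@gnnLayer %in% c("GraphSAGE", "GCN", "GAT", "GIN"))
    return("gnnLayer must be GraphSAGE, GCN, GAT or GIN")
  if (length(object@gnnDims) != 3 || any(object@gnnDims < 1))
    return("gnnDims must be three positive widths")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (!object@pooling %in% c("mean", "max"))
    return("pooling must be mean or max")
  if (any(c(object@targetKernel, object@pocketKernel) %% 2 != 1))
    return("convolution kernels must be odd")
  TRUE
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: seq=%s (kernels %d/%d -> %d), gnn=%s [%s], proj=%d, head=%d->1, dropout=%.2f, %s pooling\n",
    object@seqEncoder, object@targetKernel, object@pocketKernel,
    object@seqOutDim, object@gnnLayer,
    paste(object@gnnDims, collapse = ","), object@projectionDim,
    object@fcHidden, object@dropout, object@pooling))
})

.seqInDim <- function(config) length(config@residueVocab)

.gnnInDim <- function(config, stream) {
  if (stream == "d") return(length(config@atomVocab))
  if (config@seqEncoder == "none") .seqInDim(config) else config@seqOutDim
}

.initSeqEncoder <- function(encoder, inDim, outDim, kernel) {
  switch(encoder,
         none = list(),
         CNN = list(W = .glorot(kernel * inDim, outDim), b = numeric(outDim)),
         LSTM = list(Wx = .glorot(inDim, 4 * outDim),
                     Wh = .glorot(outDim, 4 * outDim),
                     b = numeric(4 * outDim)),
         BiLSTM = {
           h <- outDim / 2
           list(fWx = .glorot(inDim, 4 * h), fWh = .glorot(h, 4 * h),
                fb = numeric(4 * h),
                bWx = .glorot(inDim, 4 * h), bWh = .glorot(h, 4 * h),
                bb = numeric(4 * h))
         },
         CNN_LSTM = list(cW = .glorot(kernel * inDim, outDim),
                         cb = numeric(outDim),
                         Wx = .glorot(outDim, 4 * outDim),
                         Wh = .glorot(outDim, 4 * outDim),
                         b = numeric(4 * outDim)),
         stop("unknown sequence encoder: ", encoder))
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, drawn from the global RNG (seed it
#' or pass \code{seed}). The parameter count depends only on the
#' configuration, never on input sizes: the model is fully inductive.
#'
#' @param config a \code{ModelConfig}.
#' @param seed optional integer seed.
#' @return named list of parameter groups.
#' @export
initModelParams <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- config@gnnDims
  p <- list()
  for (s in c("t", "p")) {
    kern <- if (s == "t") config@targetKernel else config@pocketKernel
    p[[paste0("seq_", s)]] <- .initSeqEncoder(config@seqEncoder,
                                              .seqInDim(config),
                                              config@seqOutDim, kern)
  }
  for (s in c("d", "t", "p")) {
    nin <- .gnnInDim(config, s)
    stack <- list()
    for (l in 1:3) {
      stack[[paste0("l", l)]] <- .initGnnLayer(config@gnnLayer, nin, dims[l])
      nin <- dims[l]
    }
    p[[paste0("gnn_", s)]] <- stack
    p[[paste0("proj_", s)]] <- list(W = .glorot(dims[3],
                                                config@projectionDim),
                                    b = numeric(config@projectionDim))
  }
  p$fc1 <- list(W = .glorot(3 * config@projectionDim, config@fcHidden),
                b = numeric(config@fcHidden))
  p$fc2 <- list(W = .glorot(config@fcHidden, 1), b = numeric(1))
  p
}

# --- sequence-encoder forward/backward over one concatenated batch ---------
# For the CNN the per-sample unrolled inputs are stacked row-wise, so the
# whole batch is one matrix product. Recurrent encoders loop over samples.

.seqForward <- function(stream, p, encoder, slope) {
  if (encoder == "none")
    return(list(out = stream$H0raw, cache = NULL))
  if (encoder == "CNN") {
    cc <- .convForward(stream$Xcol, p$W, p$b, slope)
    return(list(out = cc$out, cache = cc))
  }
  outs <- vector("list", length(stream$Xlist))
  caches <- vector("list", length(stream$Xlist))
  for (k in seq_along(stream$Xlist)) {
    X <- stream$Xlist[[k]]
    if (encoder == "LSTM") {
      cc <- .lstmForward(X, p$Wx, p$Wh, p$b)
      outs[[k]] <- cc$out; caches[[k]] <- cc
    } else if (encoder == "BiLSTM") {
      fw <- .lstmForward(X, p$fWx, p$fWh, p$fb)
      rev_ <- X[rev(seq_len(nrow(X))), , drop = FALSE]
      bw <- .lstmForward(rev_, p$bWx, p$bWh, p$bb)
      outs[[k]] <- cbind(fw$out, bw$out[rev(seq_len(nrow(X))), , drop = FALSE])
      caches[[k]] <- list(fw = fw, bw = bw)
    } else if (encoder == "CNN_LSTM") {
      conv <- .convForward(.buildXcol(X, stream$kernel), p$cW, p$cb, slope)
      ll <- .lstmForward(conv$out, p$Wx, p$Wh, p$b)
      outs[[k]] <- ll$out; caches[[k]] <- list(conv = conv, lstm = ll)
    }
  }
  list(out = do.call(rbind, outs), cache = caches)
}

.seqBackward <- function(dOut, stream, cache, p, encoder, slope) {
  if (encoder == "none") return(list())
  if (encoder == "CNN") {
    bb <- .convBackward(dOut, cache, slope)
    return(list(W = bb$dW, b = bb$db))
  }
  offs <- cumsum(c(0L, stream$sizes[-length(stream$sizes)]))
  g <- NULL
  addg <- function(g, gnew) {
    if (is.null(g)) return(gnew)
    Map(`+`, g, gnew)
  }
  for (k in seq_along(stream$Xlist)) {
    idx <- offs[k] + seq_len(stream$sizes[k])
    dH <- dOut[idx, , drop = FALSE]
    if (encoder == "LSTM") {
      bb <- .lstmBackward(dH, cache[[k]], p$Wx, p$Wh, p$b)
      g <- addg(g, list(Wx = bb$dWx, Wh = bb$dWh, b = bb$db))
    } else if (encoder == "BiLSTM") {
      h <- ncol(dH) / 2
      L <- nrow(dH)
      fb <- .lstmBackward(dH[, 1:h, drop = FALSE], cache[[k]]$fw,
                          p$fWx, p$fWh, p$fb)
      bw <- .lstmBackward(dH[rev(seq_len(L)), (h + 1):(2 * h), drop = FALSE],
                          cache[[k]]$bw, p$bWx, p$bWh, p$bb)
      g <- addg(g, list(fWx = fb$dWx, fWh = fb$dWh, fb = fb$db,
                        bWx = bw$dWx, bWh = bw$dWh, bb = bw$db))
    } else if (encoder == "CNN_LSTM") {
      bl <- .lstmBackward(dH, cache[[k]]$lstm, p$Wx, p$Wh, p$b)
      bc <- .convBackward(bl$dX, cache[[k]]$conv, slope)
      g <- addg(g, list(cW = bc$dW, cb = bc$db,
                        Wx = bl$dWx, Wh = bl$dWh, b = bl$db))
    }
  }
  g
}

# --- batch preparation ------------------------------------------------------

.cacheSeqInputs <- function(sample, config) {
  ch <- sample@cache
  if (config@seqEncoder %in% c("CNN")) {
    kt <- config@targetKernel; kp <- config@pocketKernel
    keyT <- paste0("xcol_t_", kt); keyP <- paste0("xcol_p_", kp)
    if (is.null(ch[[keyT]]))
      ch[[keyT]] <- .buildXcol(vertexFeatures(sample@targetGraph), kt)
    if (is.null(ch[[keyP]]))
      ch[[keyP]] <- .buildXcol(vertexFeatures(sample@pocketGraph), kp)
  }
  ch
}

.prepareStream <- function(samples, config, stream) {
  graphs <- lapply(samples, function(s)
    slot(s, switch(stream, d = "drug", t = "targetGraph", p = "pocketGraph")))
  sizes <- vapply(graphs, nVertices, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]@edges
    if (nrow(e)) e + offsets[k] else e
  }))
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
  n <- sum(sizes)
  out <- list(sizes = sizes, offsets = offsets, n = n,
              membership = rep(seq_along(graphs), sizes),
              ops = .prepareGraphOps(config@gnnLayer, n, edges))
  if (stream == "d" || config@seqEncoder == "none") {
    out$H0raw <- do.call(rbind, lapply(graphs, vertexFeatures))
  } else if (config@seqEncoder == "CNN") {
    kern <- if (stream == "t") config@targetKernel else config@pocketKernel
    key <- paste0("xcol_", stream, "_", kern)
    out$Xcol <- do.call(rbind, lapply(samples, function(s) {
      x <- s@cache[[key]]
      if (is.null(x)) .buildXcol(vertexFeatures(
        slot(s, if (stream == "t") "targetGraph" else "pocketGraph")), kern)
      else x
    }))
  } else {
    out$kernel <- if (stream == "t") config@targetKernel
                  else config@pocketKernel
    out$Xlist <- lapply(graphs, vertexFeatures)
  }
  out
}

.prepareBatch <- function(samples, config) {
  list(d = .prepareStream(samples, config, "d"),
       t = .prepareStream(samples, config, "t"),
       p = .prepareStream(samples, config, "p"),
       y = vapply(samples, affinity, numeric(1)),
       ids = vapply(samples, function(s) s@id, character(1)),
       k = length(samples))
}

# --- full model forward / backward -----------------------------------------

.modelForward <- function(batch, params, config, training = FALSE,
                          wantAttention = FALSE) {
  slope <- config@negativeSlope
  type <- config@gnnLayer
  caches <- list()
  pooled <- list()
  for (s in c("d", "t", "p")) {
    stream <- batch[[s]]
    if (s == "d") {
      H <- stream$H0raw
      seqCache <- NULL
    } else {
      sf <- .seqForward(stream, params[[paste0("seq_", s)]],
                        config@seqEncoder, slope)
      H <- sf$out
      seqCache <- sf$cache
    }
    gnnCaches <- vector("list", 3L)
    stack <- params[[paste0("gnn_", s)]]
    for (l in 1:3) {
      cc <- .gnnForward(type, H, stream$ops, stack[[l]], slope)
      gnnCaches[[l]] <- cc
      H <- cc$out
    }
    pc <- .poolForward(H, stream$membership, stream$sizes, config@pooling)
    pp <- params[[paste0("proj_", s)]]
    P <- sweep(pc$out %*% pp$W, 2, pp$b, "+")
    caches[[s]] <- list(seq = seqCache, gnn = gnnCaches, pool = pc,
                        pooledIn = pc$out, emb = H)
    pooled[[s]] <- P
  }
  C <- cbind(pooled$d, pooled$t, pooled$p)
  Z1 <- sweep(C %*% params$fc1$W, 2, params$fc1$b, "+")
  A1 <- .leaky(Z1, slope)
  if (training && config@dropout > 0) {
    keep <- 1 - config@dropout
    mask <- matrix(rbinom(length(A1), 1, keep) / keep, nrow(A1), ncol(A1))
  } else mask <- NULL
  A1d <- if (is.null(mask)) A1 else A1 * mask
  yhat <- as.numeric(sweep(A1d %*% params$fc2$W, 2, params$fc2$b, "+"))
  if (any(!is.finite(yhat)))
    stop("non-finite prediction encountered (ids: ",
         paste(batch$ids[!is.finite(yhat)], collapse = ","), ")")
  att <- NULL
  if (wantAttention) {
    att <- lapply(seq_len(batch$k), function(kk) {
      di <- batch$d$offsets[kk] + seq_len(batch$d$sizes[kk])
      ti <- batch$t$offsets[kk] + seq_len(batch$t$sizes[kk])
      bidirectionalAttention(caches$d$emb[di, , drop = FALSE],
                             caches$t$emb[ti, , drop = FALSE])
    })
  }
  list(yhat = yhat, caches = caches, C = C, Z1 = Z1, A1 = A1, mask = mask,
       attention = att)
}

.modelBackward <- function(fw, batch, params, config, dy) {
  slope <- config@negativeSlope
  type <- config@gnnLayer
  grads <- list()
  dy <- matrix(dy, ncol = 1)
  A1d <- if (is.null(fw$mask)) fw$A1 else fw$A1 * fw$mask
  grads$fc2 <- list(W = crossprod(A1d, dy), b = sum(dy))
  dA1 <- dy %*% t(params$fc2$W)
  if (!is.null(fw$mask)) dA1 <- dA1 * fw$mask
  dZ1 <- dA1 * .dleaky(fw$Z1, slope)
  grads$fc1 <- list(W = crossprod(fw$C, dZ1), b = colSums(dZ1))
  dC <- dZ1 %*% t(params$fc1$W)
  pd <- config@projectionDim
  for (s in c("d", "t", "p")) {
    col0 <- switch(s, d = 0L, t = pd, p = 2L * pd)
    dP <- dC[, col0 + seq_len(pd), drop = FALSE]
    stream <- batch[[s]]
    cc <- fw$caches[[s]]
    pp <- params[[paste0("proj_", s)]]
    grads[[paste0("proj_", s)]] <- list(W = crossprod(cc$pooledIn, dP),
                                        b = colSums(dP))
    dPooled <- dP %*% t(pp$W)
    dH <- .poolBackward(dPooled, cc$pool, stream$n, config@pooling)
    stack <- params[[paste0("gnn_", s)]]
    gstack <- setNames(vector("list", 3L), c("l1", "l2", "l3"))
    for (l in 3:1) {
      bb <- .gnnBackward(type, dH, cc$gnn[[l]], stream$ops, stack[[l]],
                         slope)
      gstack[[l]] <- bb$grads
      dH <- bb$dH
    }
    grads[[paste0("gnn_", s)]] <- gstack
    if (s != "d") {
      sg <- .seqBackward(dH, stream, cc$seq,
                         params[[paste0("seq_", s)]], config@seqEncoder,
                         slope)
      if (length(sg)) grads[[paste0("seq_", s)]] <- sg
    }
  }
  grads
}

# --- exported operation-level functions -------------------------------------

#' Encode a sequence feature matrix
#'
#' Runs one sequence encoder over an L x d feature matrix (or an
#' \linkS4class{EncodedSequence}) and returns the L x outDim encoding.
#' CNN: 1D convolution, zero 'same' padding, stride 1, so the output length
#' equals L; rows beyond a padded input's true length are sliced off by the
#' caller. Standalone use initializes fresh seeded weights; pass
#' \code{params} to reuse trained ones.
#'
#' @param features L x d matrix or \linkS4class{EncodedSequence}.
#' @param encoder \code{"CNN"}, \code{"LSTM"}, \code{"BiLSTM"} or
#'   \code{"CNN_LSTM"}.
#' @param kernel convolution kernel size.
#' @param outDim output channels.
#' @param params optional encoder parameter list.
#' @param seed seed for fresh weights when \code{params} is NULL.
#' @param negativeSlope LeakyReLU slope.
#' @return L x outDim numeric matrix.
#' @export
encodeSequence <- function(features, encoder = "CNN", kernel = 5,
                           outDim = 128, params = NULL, seed = 1,
                           negativeSlope = 0.01) {
  X <- if (is(features, "EncodedSequence")) encodedMatrix(features)
       else as.matrix(features)
  if (nrow(X) < 1) stop("sequence must have at least one row")
  if (is.null(params)) {
    set.seed(seed)
    params <- .initSeqEncoder(encoder, ncol(X), outDim, kernel)
  }
  stream <- list(Xcol = if (encoder == "CNN") .buildXcol(X, kernel),
                 Xlist = list(X), sizes = nrow(X), kernel = kernel)
  .seqForward(stream, params, encoder, negativeSlope)$out
}

#' Encode a graph with a 3-layer GNN stack
#'
#' Three message-passing layers (LeakyReLU after each) followed by a
#' permutation-invariant readout. GraphSAGE aggregates the neighbor mean
#' plus an explicit self term; GCN uses the symmetrically normalized
#' adjacency with self-loops; GAT a single attention head; GIN a sum
#' aggregator with a two-layer MLP update.
#'
#' @param graph a \linkS4class{SimpleGraph}.
#' @param layerType GNN family.
#' @param dims three layer widths.
#' @param pooling \code{"mean"} or \code{"max"}.
#' @param params optional list of three layer-parameter lists.
#' @param seed seed for fresh weights when \code{params} is NULL.
#' @param negativeSlope LeakyReLU slope.
#' @return list with \code{vertexEmbeddings} (n x dims[3]) and \code{pooled}
#'   (length dims[3] vector).
#' @export
encodeGraph <- function(graph, layerType = "GraphSAGE",
                        dims = c(32, 64, 128), pooling = "mean",
                        params = NULL, seed = 1, negativeSlope = 0.01) {
  if (nVertices(graph) < 1) stop("cannot encode an empty graph")
  H <- vertexFeatures(graph)
  if (is.null(params)) {
    set.seed(seed)
    params <- list()
    nin <- ncol(H)
    for (l in 1:3) {
      params[[l]] <- .initGnnLayer(layerType, nin, dims[l])
      nin <- dims[l]
    }
  }
  ops <- .prepareGraphOps(layerType, nVertices(graph), graph@edges)
  for (l in 1:3)
    H <- .gnnForward(layerType, H, ops, params[[l]], negativeSlope)$out
  pooled <- .poolForward(H, rep(1L, nrow(H)), nrow(H), pooling)$out
  list(vertexEmbeddings = H, pooled = as.numeric(pooled))
}

#' Project a pooled graph embedding
#'
#' The per-stream affine map from the readout width to the projection width
#' (weights are not shared between the drug, target and pocket streams).
#'
#' @param pooled numeric vector (or k x d matrix of pooled embeddings).
#' @param W,b projection weights (d x p matrix, length-p bias).
#' @return projected vector / matrix.
#' @export
projectEmbedding <- function(pooled, W, b) {
  x <- if (is.matrix(pooled)) pooled else matrix(pooled, nrow = 1)
  if (ncol(x) != nrow(W)) stop("projection input width ", ncol(x),
                               " does not match weights (", nrow(W), ")")
  out <- sweep(x %*% W, 2, b, "+")
  if (is.matrix(pooled)) out else as.numeric(out)
}

#' Fuse projected stream embeddings and predict affinity
#'
#' Concatenates the three projected vectors (to 3 x projectionDim = 768 by
#' default), applies linear -> LeakyReLU -> dropout -> linear and returns
#' the scalar pKd prediction. Dropout is active only with
#' \code{training = TRUE}.
#'
#' @param drug,target,pocket projected embedding vectors.
#' @param params full model parameter list (uses \code{fc1}, \code{fc2}).
#' @param dropout dropout rate.
#' @param training enable dropout.
#' @param negativeSlope LeakyReLU slope.
#' @return predicted pKd (finite scalar).
#' @export
fusePredict <- function(drug, target, pocket, params, dropout = 0,
                        training = FALSE, negativeSlope = 0.01) {
  C <- matrix(c(drug, target, pocket), nrow = 1)
  if (ncol(C) != nrow(params$fc1$W))
    stop("fusion input width ", ncol(C), " does not match fc1 (",
         nrow(params$fc1$W), ")")
  Z1 <- sweep(C %*% params$fc1$W, 2, params$fc1$b, "+")
  A1 <- .leaky(Z1, negativeSlope)
  if (training && dropout > 0) {
    keep <- 1 - dropout
    A1 <- A1 * matrix(rbinom(length(A1), 1, keep) / keep, 1)
  }
  y <- as.numeric(A1 %*% params$fc2$W + params$fc2$b)
  if (!is.finite(y)) stop("non-finite prediction")
  y
}

#' Run the full model on one featurized complex
#'
#' Sequence-encodes the target and pocket (vertex features = sliced encoder
#' output; the drug keeps its one-hot atom features), runs the three GNN
#' streams, fuses and predicts. With \code{attention = TRUE} the
#' bidirectional attention between the pre-pooling drug and target vertex
#' embeddings is returned as well.
#'
#' @param sample a \linkS4class{ComplexSample}.
#' @param params model parameters from \code{\link{initModelParams}} or
#'   training.
#' @param config the \code{ModelConfig} the parameters were built with.
#' @param attention also compute the attention matrices.
#' @return list with \code{prediction} and optionally \code{attention}
#'   (an \linkS4class{AttentionResult}).
#' @export
forwardComplex <- function(sample, params, config = modelConfig(),
                           attention = FALSE) {
  batch <- .prepareBatch(list(sample), config)
  fw <- .modelForward(batch, params, config, training = FALSE,
                      wantAttention = attention)
  list(prediction = fw$yhat[1],
       attention = if (attention) fw$attention[[1]])
}

#' Bidirectional scaled-dot-product attention
#'
#' Scores S = drugEmb %*% t(targetEmb) / sqrt(d); atoms-to-residues is the
#' row softmax of S, residues-to-atoms the row softmax of t(S). Both are
#' row-stochastic; the per-row ranking is invariant to adding a constant to
#' a row of S.
#'
#' @param drugEmb n_atoms x d matrix of atom embeddings.
#' @param targetEmb n_residues x d matrix of residue embeddings.
#' @return an \linkS4class{AttentionResult}.
#' @export
bidirectionalAttention <- function(drugEmb, targetEmb) {
  drugEmb <- as.matrix(drugEmb); targetEmb <- as.matrix(targetEmb)
  if (!nrow(drugEmb) || !nrow(targetEmb)) stop("empty embedding matrix")
  if (ncol(drugEmb) != ncol(targetEmb))
    stop("embedding dimensions differ: ", ncol(drugEmb), " vs ",
         ncol(targetEmb))
  S <- drugEmb %*% t(targetEmb) / sqrt(ncol(drugEmb))
  rowSoftmax <- function(M) {
    M <- M - apply(M, 1, max)
    E <- exp(M)
    E / rowSums(E)
  }
  new("AttentionResult", atomsToResidues = rowSoftmax(S),
      residuesToAtoms = rowSoftmax(t(S)))
}

#' Count model parameters
#'
#' @param params parameter list.
#' @return total number of scalar parameters.
#' @export
countParams <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(params)
  n
}
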