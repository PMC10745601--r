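# Low-level neural-network layers with explicit forward/backward passes.
# There is no autograd here: every layer returns a cache from its forward
# pass and a matching backward function computes input and parameter
# gradients analytically. Gradient correctness is pinned against
# finite-difference oracles in the test suite.

.leaky <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

.dleaky <- function(x, slope = 0.01) {
  d <- matrix(1, nrow(x), ncol(x))
  d[x < 0] <- slope
  d
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# --- 1D convolution as an unrolled matrix product -------------------------
# A length-L sequence with d channels and odd kernel k is convolved with
# zero 'same' padding by building the L x (k*d) unrolled input ("Xcol");
# the convolution is then Xcol %*% W with W of shape (k*d) x filters.

.buildXcol <- function(X, kernel) {
  if (kernel %% 2 == 0) stop("convolution kernel must be odd")
  L <- nrow(X); d <- ncol(X)
  h <- (kernel - 1L) / 2L
  Xp <- rbind(matrix(0, h, d), X, matrix(0, h, d))
  do.call(cbind, lapply(0:(kernel - 1L), function(off)
    Xp[(1L + off):(L + off), , drop = FALSE]))
}

.convForward <- function(Xcol, W, b, slope) {
  Z <- Xcol %*% W
  Z <- sweep(Z, 2, b, "+")
  list(out = .leaky(Z, slope), Z = Z, Xcol = Xcol)
}

.convBackward <- function(dOut, cache, slope) {
  dZ <- dOut * .dleaky(cache$Z, slope)
  list(dW = crossprod(cache$Xcol, dZ), db = colSums(dZ),
       dXcol = dZ)   # propagated only when an LSTM sits on top
}

# --- LSTM (single direction) ----------------------------------------------
# Gate order in the stacked weight matrices: input, forget, cell, output.

.sigm <- function(x) 1 / (1 + exp(-x))

.lstmForward <- function(X, Wx, Wh, b) {
  L <- nrow(X); H <- ncol(Wh) / 4L
  hs <- matrix(0, L, H); cs <- matrix(0, L, H)
  gates <- matrix(0, L, 4L * H)
  h <- numeric(H); cprev <- numeric(H)
  XW <- X %*% Wx
  for (t in seq_len(L)) {
    a <- XW[t, ] + as.numeric(h %*% Wh) + b
    i <- .sigm(a[1:H]); f <- .sigm(a[(H + 1):(2 * H)])
    g <- tanh(a[(2 * H + 1):(3 * H)]); o <- .sigm(a[(3 * H + 1):(4 * H)])
    cc <- f * cprev + i * g
    h <- o * tanh(cc)
    hs[t, ] <- h; cs[t, ] <- cc
    gates[t, ] <- c(i, f, g, o)
    cprev <- cc
  }
  list(out = hs, cs = cs, gates = gates, X = X)
}

.lstmBackward <- function(dH, cache, Wx, Wh, b) {
  X <- cache$X; hs <- cache$out
  gates <- cache$gates; csmat <- cache$cs
  L <- nrow(X); H <- ncol(hs)
  dWx <- matrix(0, nrow(Wx), ncol(Wx)); dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H); dX <- matrix(0, L, ncol(X))
  dhnext <- numeric(H); dcnext <- numeric(H)
  for (t in rev(seq_len(L))) {
    i <- gates[t, 1:H]; f <- gates[t, (H + 1):(2 * H)]
    g <- gates[t, (2 * H + 1):(3 * H)]; o <- gates[t, (3 * H + 1):(4 * H)]
    cc <- csmat[t, ]
    cprev <- if (t > 1) csmat[t - 1, ] else numeric(H)
    hprev <- if (t > 1) hs[t - 1, ] else numeric(H)
    dh <- dH[t, ] + dhnext
    tc <- tanh(cc)
    do_ <- dh * tc * o * (1 - o)
    dc <- dh * o * (1 - tc^2) + dcnext
    di <- dc * g * i * (1 - i)
    df <- dc * cprev * f * (1 - f)
    dg <- dc * i * (1 - g^2)
    da <- c(di, df, dg, do_)
    dWx <- dWx + outer(X[t, ], da)
    dWh <- dWh + outer(hprev, da)
    db <- db + da
    dX[t, ] <- da %*% t(Wx)
    dhnext <- as.numeric(da %*% t(Wh))
    dcnext <- dc * f
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# --- GNN layers (operate on a whole batched vertex set) -------------------
# ops: precomputed sparse operators / edge arrays from .prepareGraphOps.

.sageForward <- function(H, ops, p, slope) {
  Hn <- as.matrix(ops$Amean %*% H)
  Z <- H %*% p$Ws + Hn %*% p$Wn
  Z <- sweep(Z, 2, p$b, "+")
  list(out = .leaky(Z, slope), Z = Z, H = H, Hn = Hn)
}

.sageBackward <- function(dOut, cache, ops, p, slope) {
  dZ <- dOut * .dleaky(cache$Z, slope)
  dH <- dZ %*% t(p$Ws) + as.matrix(Matrix::t(ops$Amean) %*% (dZ %*% t(p$Wn)))
  list(grads = list(Ws = crossprod(cache$H, dZ),
                    Wn = crossprod(cache$Hn, dZ), b = colSums(dZ)),
       dH = dH)
}

.gcnForward <- function(H, ops, p, slope) {
  AH <- as.matrix(ops$Ahat %*% H)
  Z <- AH %*% p$W
  Z <- sweep(Z, 2, p$b, "+")
  list(out = .leaky(Z, slope), Z = Z, AH = AH)
}

.gcnBackward <- function(dOut, cache, ops, p, slope) {
  dZ <- dOut * .dleaky(cache$Z, slope)
  dH <- as.matrix(Matrix::t(ops$Ahat) %*% (dZ %*% t(p$W)))
  list(grads = list(W = crossprod(cache$AH, dZ), b = colSums(dZ)), dH = dH)
}

.ginForward <- function(H, ops, p, slope) {
  S <- H + as.matrix(ops$Asum %*% H)   # (1 + eps) with eps fixed at 0
  Z1 <- sweep(S %*% p$W1, 2, p$b1, "+")
  R <- .leaky(Z1, slope)
  Z2 <- sweep(R %*% p$W2, 2, p$b2, "+")
  list(out = .leaky(Z2, slope), Z1 = Z1, Z2 = Z2, S = S, R = R)
}

.ginBackward <- function(dOut, cache, ops, p, slope) {
  dZ2 <- dOut * .dleaky(cache$Z2, slope)
  dR <- dZ2 %*% t(p$W2)
  dZ1 <- dR * .dleaky(cache$Z1, slope)
  dS <- dZ1 %*% t(p$W1)
  dH <- dS + as.matrix(Matrix::t(ops$Asum) %*% dS)
  list(grads = list(W1 = crossprod(cache$S, dZ1), b1 = colSums(dZ1),
                    W2 = crossprod(cache$R, dZ2), b2 = colSums(dZ2)),
       dH = dH)
}

# Single-head graph attention. Edge arrays ops$src/ops$dst are directed and
# include self-loops, so every vertex appears in both roles and the segment
# softmax over incoming edges is always defined. The attention logits use
# the customary LeakyReLU with slope 0.2, independent of the model-wide
# activation slope.
.gatForward <- function(H, ops, p, slope) {
  G <- H %*% p$W
  t1 <- as.numeric(G %*% p$a1)   # destination term
  t2 <- as.numeric(G %*% p$a2)   # source term
  pre <- t1[ops$dst] + t2[ops$src]
  act <- .leaky(matrix(pre), 0.2)[, 1]
  mx <- tapply(act, ops$dst, max)
  ex <- exp(act - as.numeric(mx[as.character(ops$dst)]))
  denom <- rowsum(ex, ops$dst)[, 1]
  alpha <- as.numeric(ex / denom[as.character(ops$dst)])
  agg <- rowsum(alpha * G[ops$src, , drop = FALSE], ops$dst)
  Z <- sweep(agg, 2, p$b, "+")
  list(out = .leaky(Z, slope), Z = Z, G = G, alpha = alpha, pre = pre,
       H = H)
}

.gatBackward <- function(dOut, cache, ops, p, slope) {
  dZ <- dOut * .dleaky(cache$Z, slope)
  G <- cache$G; alpha <- cache$alpha
  src <- ops$src; dst <- ops$dst
  dalpha <- rowSums(dZ[dst, , drop = FALSE] * G[src, , drop = FALSE])
  dG <- rowsum(alpha * dZ[dst, , drop = FALSE], src)
  seg <- rowsum(alpha * dalpha, dst)[, 1]
  de <- alpha * (dalpha - seg[as.character(dst)])
  dpre <- de * ifelse(cache$pre < 0, 0.2, 1)
  dt1 <- rowsum(dpre, dst)[, 1]
  dt2 <- rowsum(dpre, src)[, 1]
  dG <- dG + outer(dt1, p$a1) + outer(dt2, p$a2)
  list(grads = list(W = crossprod(cache$H, dG),
                    a1 = as.numeric(crossprod(G, dt1)),
                    a2 = as.numeric(crossprod(G, dt2)),
                    b = colSums(dZ)),
       dH = dG %*% t(p$W))
}

.gnnForward <- function(type, H, ops, p, slope) {
  switch(type,
         GraphSAGE = .sageForward(H, ops, p, slope),
         GCN = .gcnForward(H, ops, p, slope),
         GIN = .ginForward(H, ops, p, slope),
         GAT = .gatForward(H, ops, p, slope),
         stop("unknown GNN layer type: ", type))
}

.gnnBackward <- function(type, dOut, cache, ops, p, slope) {
  switch(type,
         GraphSAGE = .sageBackward(dOut, cache, ops, p, slope),
         GCN = .gcnBackward(dOut, cache, ops, p, slope),
         GIN = .ginBackward(dOut, cache, ops, p, slope),
         GAT = .gatBackward(dOut, cache, ops, p, slope))
}

.initGnnLayer <- function(type, nin, nout) {
  switch(type,
         GraphSAGE = list(Ws = .glorot(nin, nout), Wn = .glorot(nin, nout),
                          b = numeric(nout)),
         GCN = list(W = .glorot(nin, nout), b = numeric(nout)),
         GIN = list(W1 = .glorot(nin, nout), b1 = numeric(nout),
                    W2 = .glorot(nout, nout), b2 = numeric(nout)),
         GAT = list(W = .glorot(nin, nout),
                    a1 = runif(nout, -sqrt(6 / (nout + 1)),
                               sqrt(6 / (nout + 1))),
                    a2 = runif(nout, -sqrt(6 / (nout + 1)),
                               sqrt(6 / (nout + 1))),
                    b = numeric(nout)),
         stop("unknown GNN layer type: ", type))
}

# Sparse operators needed by each layer family, computed once per batch
# from the undirected edge list of the (batched) graph.
.prepareGraphOps <- function(type, nVertices, edges) {
  n <- nVertices
  if (nrow(edges)) {
    src <- c(edges[, 1], edges[, 2])
    dst <- c(edges[, 2], edges[, 1])
  } else {
    src <- integer(); dst <- integer()
  }
  if (type == "GraphSAGE") {
    deg <- tabulate(dst, nbins = n)
    w <- 1 / pmax(deg[dst], 1)
    list(Amean = Matrix::sparseMatrix(i = dst, j = src, x = w,
                                      dims = c(n, n)))
  } else if (type == "GCN") {
    si <- c(src, seq_len(n)); di <- c(dst, seq_len(n))
    deg <- tabulate(di, nbins = n)
    w <- 1 / sqrt(deg[di] * deg[si])
    list(Ahat = Matrix::sparseMatrix(i = di, j = si, x = w, dims = c(n, n)))
  } else if (type == "GIN") {
    list(Asum = Matrix::sparseMatrix(i = dst, j = src, x = 1,
                                     dims = c(n, n)))
  } else if (type == "GAT") {
    list(src = c(src, seq_len(n)), dst = c(dst, seq_len(n)))
  } else stop("unknown GNN layer type: ", type)
}

# --- pooling ---------------------------------------------------------------

.poolForward <- function(H, membership, sizes, pooling) {
  k <- length(sizes)
  if (pooling == "mean") {
    M <- Matrix::sparseMatrix(i = membership, j = seq_along(membership),
                              x = 1 / sizes[membership],
                              dims = c(k, length(membership)))
    list(out = as.matrix(M %*% H), M = M)
  } else if (pooling == "max") {
    out <- matrix(-Inf, k, ncol(H))
    arg <- matrix(0L, k, ncol(H))
    for (g in seq_len(k)) {
      idx <- which(membership == g)
      sub <- H[idx, , drop = FALSE]
      w <- max.col(t(sub), ties.method = "first")
      arg[g, ] <- idx[w]
      out[g, ] <- sub[cbind(w, seq_len(ncol(H)))]
    }
    list(out = out, arg = arg)
  } else stop("unknown pooling: ", pooling)
}

.poolBackward <- function(dP, cache, nRows, pooling) {
  if (pooling == "mean") {
    as.matrix(Matrix::t(cache$M) %*% dP)
  } else {
    dH <- matrix(0, nRows, ncol(dP))
    for (g in seq_len(nrow(dP)))
      dH[cbind(cache$arg[g, ], seq_len(ncol(dP)))] <-
        dH[cbind(cache$arg[g, ], seq_len(ncol(dP)))] + dP[g, ]
    dH
  }
}
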