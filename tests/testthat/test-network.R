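test_that("CNN sequence encoding preserves length and maps zeros to zeros", {
  X <- oneHotEncode(paste(sample(defaultResidueVocab(), 10, TRUE),
                          collapse = ""))
  out <- encodeSequence(X, "CNN", kernel = 5, outDim = 128, seed = 2)
  expect_equal(dim(out), c(10L, 128L))
  zero <- encodeSequence(matrix(0, 6, 20), "CNN", kernel = 5, seed = 2)
  expect_equal(sum(abs(zero)), 0)   # zero input, zero-initialized bias
})

test_that("convolution output below the true length is padding-invariant", {
  set.seed(8)
  s <- paste(sample(defaultResidueVocab(), 40, TRUE), collapse = "")
  X <- oneHotEncode(s)
  short <- padOrTruncate(X, 45)     # true length + kernel
  long <- padOrTruncate(X, 200)     # much longer zero padding
  set.seed(11); p <- StructDTA:::.initSeqEncoder("CNN", 20, 16, 5)
  a <- encodeSequence(short, "CNN", kernel = 5, outDim = 16, params = p)
  b <- encodeSequence(long, "CNN", kernel = 5, outDim = 16, params = p)
  expect_equal(a[1:40, ], b[1:40, ], tolerance = 1e-12)
})

test_that("recurrent sequence encoders keep the length/width contract", {
  X <- oneHotEncode(paste(sample(defaultResidueVocab(), 7, TRUE),
                          collapse = ""))
  for (enc in c("LSTM", "BiLSTM", "CNN_LSTM")) {
    out <- encodeSequence(X, enc, kernel = 5, outDim = 16, seed = 3)
    expect_equal(dim(out), c(7L, 16L))
    expect_true(all(is.finite(out)))
  }
})

test_that("graph encoding pools a single vertex to its own embedding", {
  g <- new("SimpleGraph", nVertices = 1L,
           edges = matrix(integer(), ncol = 2),
           features = matrix(rnorm(27), 1, 27), labels = character())
  for (type in c("GraphSAGE", "GCN", "GAT", "GIN")) {
    enc <- encodeGraph(g, type, dims = c(4, 5, 6), seed = 4)
    expect_equal(enc$pooled, as.numeric(enc$vertexEmbeddings[1, ]))
  }
})

test_that("graph readout is invariant to vertex relabeling", {
  prot <- generateProtein(20, seed = 6)
  g <- buildResidueGraph(prot, oneHotEncode(prot@residues$code))
  set.seed(10)
  for (type in c("GraphSAGE", "GCN", "GAT", "GIN")) {
    base <- encodeGraph(g, type, dims = c(4, 5, 6), seed = 5)
    for (r in 1:3) {
      perm <- sample(nVertices(g))
      pg <- permuteGraph(g, perm)
      enc <- encodeGraph(pg, type, dims = c(4, 5, 6), seed = 5)
      expect_equal(enc$pooled, base$pooled, tolerance = 1e-5)
    }
  }
})

test_that("two disconnected identical components mean-pool like one", {
  prot <- generateProtein(12, seed = 3)
  g <- buildResidueGraph(prot, oneHotEncode(prot@residues$code))
  e <- edgeMatrix(g)
  doubled <- new("SimpleGraph", nVertices = 24L,
                 edges = rbind(e, e + 12L),
                 features = rbind(vertexFeatures(g), vertexFeatures(g)),
                 labels = character())
  one <- encodeGraph(g, "GraphSAGE", dims = c(4, 5, 6), seed = 7)
  two <- encodeGraph(doubled, "GraphSAGE", dims = c(4, 5, 6), seed = 7)
  expect_equal(two$pooled, one$pooled, tolerance = 1e-10)
})

test_that("projection is affine with the stated output width", {
  set.seed(12)
  W <- matrix(rnorm(128 * 256, sd = 0.05), 128, 256)
  b <- rnorm(256)
  expect_equal(length(projectEmbedding(rnorm(128), W, b)), 256L)
  expect_equal(projectEmbedding(numeric(128), W, numeric(256)),
               numeric(256))
  a1 <- rnorm(128); a2 <- rnorm(128)
  expect_equal(projectEmbedding(a1 + a2, W, b),
               projectEmbedding(a1, W, b) + projectEmbedding(a2, W, b) -
                 projectEmbedding(numeric(128), W, b),
               tolerance = 1e-10)
  expect_error(projectEmbedding(rnorm(64), W, b), "width")
})

test_that("fusion head returns a finite deterministic scalar in eval mode", {
  cfg <- modelConfig()
  params <- initModelParams(cfg, seed = 20)
  set.seed(1)
  d <- rnorm(256); t <- rnorm(256); p <- rnorm(256)
  y1 <- fusePredict(d, t, p, params)
  y2 <- fusePredict(d, t, p, params)
  expect_true(is.finite(y1))
  expect_identical(y1, y2)
  expect_error(fusePredict(rnorm(10), t, p, params), "width")
})

test_that("full forward runs on a synthetic complex and respects atom order", {
  cfg <- modelConfig()
  params <- initModelParams(cfg, seed = 21)
  s <- makeSample(301, nres = 30, psize = 10, natoms = 8, cfg = cfg)
  base <- forwardComplex(s, params, cfg)$prediction
  expect_true(is.finite(base))
  set.seed(33)
  for (r in 1:3) {
    s2 <- s
    s2@drug <- permuteGraph(s@drug, sample(nVertices(s@drug)))
    expect_equal(forwardComplex(s2, params, cfg)$prediction, base,
                 tolerance = 1e-5)
  }
})

test_that("seq_encoder none feeds one-hot features straight to the GNN", {
  cfg <- modelConfig(seqEncoder = "none")
  params <- initModelParams(cfg, seed = 22)
  # first GNN layer sized for 20-dim vertex features
  expect_equal(nrow(params$gnn_t$l1$Ws), 20L)
  s <- makeSample(302, cfg = cfg)
  expect_true(is.finite(forwardComplex(s, params, cfg)$prediction))
})

test_that("prediction is invariant to batch composition in eval mode", {
  cfg <- modelConfig()
  params <- initModelParams(cfg, seed = 23)
  samples <- makeSamples(4, seedBase = 310, cfg = cfg)
  fit <- list(params = params, config = cfg)
  together <- predictAffinity(fit, samples)$y_pred
  alone <- vapply(samples, function(s)
    forwardComplex(s, params, cfg)$prediction, numeric(1))
  expect_equal(together, alone, tolerance = 1e-5)
})

test_that("bidirectional attention is row-stochastic and matches the softmax oracle", {
  set.seed(14)
  D <- matrix(rnorm(2 * 128), 2, 128)
  T <- matrix(rnorm(3 * 128), 3, 128)
  att <- bidirectionalAttention(D, T)
  expect_equal(rowSums(atomsToResidues(att)), rep(1, 2), tolerance = 1e-6)
  expect_equal(rowSums(residuesToAtoms(att)), rep(1, 3), tolerance = 1e-6)
  oracle <- bruteAttention(D, T)
  expect_equal(atomsToResidues(att), oracle$a2r, tolerance = 1e-10)
  expect_equal(residuesToAtoms(att), oracle$r2a, tolerance = 1e-10)

  # identical residue embeddings -> uniform attention rows
  Tsame <- matrix(rep(rnorm(128), each = 5), 5, 128)
  uni <- bidirectionalAttention(D, Tsame)
  expect_equal(atomsToResidues(uni),
               matrix(1 / 5, 2, 5), tolerance = 1e-10)
  expect_error(bidirectionalAttention(D, matrix(0, 3, 64)), "dimension")
})

test_that("attention ranking is invariant to per-row constant shifts", {
  set.seed(15)
  S <- matrix(rnorm(12), 3, 4)
  shifted <- S + c(5, -2, 0.3)   # constant added per row
  sm <- function(M) t(apply(M, 1, function(v) exp(v - max(v)) / sum(exp(v - max(v)))))
  expect_equal(topKRows(sm(S), 2), topKRows(sm(shifted), 2))
})

test_that("analytic gradients match finite differences for every architecture", {
  samples <- makeSamples(3, seedBase = 400, nres = 12, psize = 5, natoms = 6)
  variants <- list(
    list(cfg = modelConfig(gnnDims = c(4, 5, 6), seqOutDim = 8,
                           projectionDim = 7, fcHidden = 9),
         paths = list(c("seq_t", "W"), c("gnn_t", "l2", "Wn"),
                      c("gnn_d", "l1", "Ws"), c("fc1", "W"))),
    list(cfg = modelConfig(gnnLayer = "GCN", gnnDims = c(4, 5, 6),
                           seqOutDim = 8, projectionDim = 7, fcHidden = 9),
         paths = list(c("gnn_t", "l1", "W"), c("gnn_p", "l3", "W"))),
    list(cfg = modelConfig(gnnLayer = "GIN", gnnDims = c(4, 5, 6),
                           seqOutDim = 8, projectionDim = 7, fcHidden = 9),
         paths = list(c("gnn_t", "l1", "W1"), c("gnn_d", "l2", "W2"))),
    list(cfg = modelConfig(gnnLayer = "GAT", gnnDims = c(4, 5, 6),
                           seqOutDim = 8, projectionDim = 7, fcHidden = 9),
         paths = list(c("gnn_t", "l1", "W"), c("gnn_t", "l1", "a1"),
                      c("gnn_d", "l2", "a2"))),
    list(cfg = modelConfig(seqEncoder = "none", gnnDims = c(4, 5, 6),
                           projectionDim = 7, fcHidden = 9),
         paths = list(c("gnn_t", "l1", "Ws"))),
    list(cfg = modelConfig(seqEncoder = "LSTM", gnnDims = c(4, 5, 6),
                           seqOutDim = 8, projectionDim = 7, fcHidden = 9),
         paths = list(c("seq_t", "Wx"), c("seq_t", "Wh"))),
    list(cfg = modelConfig(seqEncoder = "BiLSTM", gnnDims = c(4, 5, 6),
                           seqOutDim = 8, projectionDim = 7, fcHidden = 9),
         paths = list(c("seq_t", "fWx"), c("seq_p", "bWh"))),
    list(cfg = modelConfig(seqEncoder = "CNN_LSTM", gnnDims = c(4, 5, 6),
                           seqOutDim = 8, projectionDim = 7, fcHidden = 9),
         paths = list(c("seq_t", "cW"), c("seq_t", "Wx"))))
  for (v in variants) {
    cfg <- v$cfg
    ss <- lapply(samples, function(s) {
      s@cache <- StructDTA:::.cacheSeqInputs(s, cfg); s
    })
    params <- initModelParams(cfg, seed = 31)
    batch <- StructDTA:::.prepareBatch(ss, cfg)
    fw <- StructDTA:::.modelForward(batch, params, cfg)
    grads <- StructDTA:::.modelBackward(fw, batch, params, cfg,
                                        dy = 2 * (fw$yhat - batch$y) /
                                          batch$k)
    lossAt <- function(p)
      mean((StructDTA:::.modelForward(batch, p, cfg)$yhat - batch$y)^2)
    set.seed(32)
    for (path in v$paths) {
      leaf <- Reduce(function(x, nm) x[[nm]], path, params)
      key <- paste(path, collapse = ".")
      for (ii in sample(length(leaf), min(2, length(leaf)))) {
        eps <- 1e-5
        l2 <- leaf; l2[ii] <- l2[ii] + eps
        lp <- lossAt(StructDTA:::.unflattenInto(params,
                                                setNames(list(l2), key)))
        l2[ii] <- l2[ii] - 2 * eps
        lm <- lossAt(StructDTA:::.unflattenInto(params,
                                                setNames(list(l2), key)))
        num <- (lp - lm) / (2 * eps)
        ana <- Reduce(function(x, nm) x[[nm]], path, grads)[ii]
        expect_equal(ana, num, tolerance = 1e-3,
                     label = paste(cfg@gnnLayer, cfg@seqEncoder, key, ii))
      }
    }
  }
})

test_that("parameter count depends on the config, not on input sizes", {
  cfg <- modelConfig()
  n1 <- countParams(initModelParams(cfg, seed = 1))
  n2 <- countParams(initModelParams(cfg, seed = 99))
  expect_equal(n1, n2)
  # the same parameters run on graphs of unseen sizes
  params <- initModelParams(cfg, seed = 1)
  small <- makeSample(501, nres = 15, psize = 6, natoms = 4, cfg = cfg)
  large <- makeSample(502, nres = 55, psize = 14, natoms = 14, cfg = cfg)
  expect_true(is.finite(forwardComplex(small, params, cfg)$prediction))
  expect_true(is.finite(forwardComplex(large, params, cfg)$prediction))
})
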