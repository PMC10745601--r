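# Shared fixtures, built in code at test time.

writeTempFile <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal 3-residue PDB: ALA, GLY, VAL with one CA each, plus noise records
fixturePDB <- function() {
  writeTempFile(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  N   VAL A   3       8.000   1.000   0.000  1.00  0.00           N",
    "ATOM      5  CA  VAL A   3       8.600   0.000   0.000  1.00  0.00           C",
    "HETATM    6  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), ".pdb")
}

fixtureEthanolSDF <- function() {
  writeTempFile(c(
    "ethanol", "  fixture", "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "   -0.8880    0.1650    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.4580   -0.5150    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5610    0.4110    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.7000    0.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.0000   -0.5000    0.9000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.0000   -0.5000   -0.9000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5000   -1.2000    0.9000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5000   -1.2000   -0.9000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.4000   -0.1000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "  1  4  1  0", "  1  5  1  0",
    "  1  6  1  0", "  2  7  1  0", "  2  8  1  0", "  3  9  1  0",
    "M  END", "$$$$"), ".sdf")
}

fixtureEthanolMOL2 <- function() {
  writeTempFile(c(
    "@<TRIPOS>MOLECULE", "ethanol", " 9 8 1 0 0", "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    "      1 C1         -0.8880    0.1650    0.0000 C.3     1  LIG1        0.0000",
    "      2 C2          0.4580   -0.5150    0.0000 C.3     1  LIG1        0.0000",
    "      3 O1          1.5610    0.4110    0.0000 O.3     1  LIG1        0.0000",
    "      4 H1         -1.7000    0.9000    0.0000 H       1  LIG1        0.0000",
    "      5 H2         -1.0000   -0.5000    0.9000 H       1  LIG1        0.0000",
    "      6 H3         -1.0000   -0.5000   -0.9000 H       1  LIG1        0.0000",
    "      7 H4          0.5000   -1.2000    0.9000 H       1  LIG1        0.0000",
    "      8 H5          0.5000   -1.2000   -0.9000 H       1  LIG1        0.0000",
    "      9 H6          2.4000   -0.1000    0.0000 H       1  LIG1        0.0000",
    "@<TRIPOS>BOND",
    "     1    1    2 1", "     2    2    3 1", "     3    1    4 1",
    "     4    1    5 1", "     5    1    6 1", "     6    2    7 1",
    "     7    2    8 1", "     8    3    9 1"), ".mol2")
}

# Build a featurized synthetic complex entirely in memory.
makeSample <- function(seed, nres = 30, psize = 10, natoms = 8,
                       cfg = modelConfig(), affinity = NULL) {
  set.seed(seed)
  prot <- generateProtein(nres, id = paste0("s", seed))
  lig <- generateLigand(natoms, id = paste0("s", seed))
  pstart <- sample(seq_len(nres - psize + 1L), 1)
  pidx <- pstart:(pstart + psize - 1L)
  if (is.null(affinity))
    affinity <- plantedAffinity(prot@residues$code[pidx])
  rv <- cfg@residueVocab
  tg <- buildResidueGraph(prot, oneHotEncode(prot@residues$code, rv),
                          cutoff = cfg@contactCutoff)
  pstruct <- new("ProteinStructure", id = "pocket",
                 residues = prot@residues[pidx, , drop = FALSE],
                 chains = "A", nSkipped = 0L)
  pg <- buildResidueGraph(pstruct,
                          oneHotEncode(pstruct@residues$code, rv),
                          cutoff = cfg@contactCutoff)
  dg <- buildMolecularGraph(lig, cfg@atomVocab)
  s <- new("ComplexSample", id = paste0("s", seed), affinity = affinity,
           protein = prot, pocketIndex = as.integer(pidx), drug = dg,
           targetGraph = tg, pocketGraph = pg, cache = list())
  s@cache <- StructDTA:::.cacheSeqInputs(s, cfg)
  s
}

makeSamples <- function(n, seedBase = 100, cfg = modelConfig(), ...) {
  lapply(seq_len(n), function(i) makeSample(seedBase + i, cfg = cfg, ...))
}

# permute the vertices of a SimpleGraph consistently (features, edges,
# labels); used for permutation-invariance checks
permuteGraph <- function(g, perm) {
  inv <- order(perm)   # vertex v moves to position inv[v]
  e <- edgeMatrix(g)
  if (nrow(e)) e <- cbind(inv[e[, 1]], inv[e[, 2]])
  new("SimpleGraph", nVertices = nVertices(g),
      edges = StructDTA:::.normalizeEdges(e),
      features = vertexFeatures(g)[perm, , drop = FALSE],
      labels = if (length(vertexLabels(g))) vertexLabels(g)[perm]
               else character())
}

# independent brute-force oracles -------------------------------------------

bruteContactEdges <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

naiveMetrics <- function(yt, yp) {
  n <- length(yt)
  mae <- sum(abs(yp - yt)) / n
  rmse <- sqrt(sum((yp - yt)^2) / n)
  pcc <- sum((yt - mean(yt)) * (yp - mean(yp))) /
    sqrt(sum((yt - mean(yt))^2) * sum((yp - mean(yp))^2))
  rk <- function(v) {   # average ranks for ties, by definition
    sapply(seq_along(v), function(i)
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2)
  }
  rt <- rk(yt); rp <- rk(yp)
  sp <- sum((rt - mean(rt)) * (rp - mean(rp))) /
    sqrt(sum((rt - mean(rt))^2) * sum((rp - mean(rp))^2))
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (yt[i] == yt[j]) next
    den <- den + 1
    if (yp[i] == yp[j]) num <- num + 0.5
    else if ((yp[i] < yp[j]) == (yt[i] < yt[j])) num <- num + 1
  }
  list(mae = mae, rmse = rmse, pcc = pcc, spearman = sp,
       ci = num / den, r2 = 1 - sum((yp - yt)^2) / sum((yt - mean(yt))^2))
}

bruteAttention <- function(D, T) {
  S <- matrix(0, nrow(D), nrow(T))
  for (i in seq_len(nrow(D))) for (j in seq_len(nrow(T)))
    S[i, j] <- sum(D[i, ] * T[j, ]) / sqrt(ncol(D))
  sm <- function(v) exp(v - max(v)) / sum(exp(v - max(v)))
  a2r <- t(apply(S, 1, sm))
  r2a <- t(apply(t(S), 1, sm))
  list(a2r = a2r, r2a = r2a)
}
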