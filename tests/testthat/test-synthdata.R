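test_that("synthetic chains keep the 3.8 A step and self-avoidance clearance", {
  prot <- generateProtein(50, seed = 71)
  xyz <- caCoords(prot)
  steps <- sqrt(rowSums((xyz[-1, ] - xyz[-50, ])^2))
  expect_equal(steps, rep(3.8, 49), tolerance = 1e-6)
  d <- as.matrix(dist(xyz))
  nonconsec <- abs(row(d) - col(d)) > 1
  expect_true(all(d[nonconsec & upper.tri(d)] >= 3.5))
})

test_that("protein generation is seed-reproducible", {
  a <- generateProtein(30, seed = 72)
  b <- generateProtein(30, seed = 72)
  c <- generateProtein(30, seed = 73)
  expect_identical(a@residues, b@residues)
  expect_false(identical(a@residues, c@residues))
})

test_that("synthetic proteins round-trip through the PDB reader", {
  prot <- generateProtein(40, seed = 74)
  path <- tempfile(fileext = ".pdb")
  writeProteinPDB(prot, path)
  back <- readProteinStructure(path)
  expect_equal(proteinSequence(back), proteinSequence(prot))
  expect_equal(skipCount(back), 0L)
  expect_equal(caCoords(back), caCoords(prot), tolerance = 1e-3,
               ignore_attr = TRUE)   # PDB column precision
})

test_that("synthetic ligands are connected with n-1..n+1 bonds and round-trip", {
  for (seed in 75:79) {
    n <- 5 + seed %% 8
    lig <- generateLigand(n, seed = seed)
    b <- bondTable(lig)
    expect_gte(nrow(b), n - 1)
    expect_lte(nrow(b), n + 1)
    # connectivity by BFS over the bond list
    adj <- lapply(seq_len(n), function(i)
      c(b$j[b$i == i], b$i[b$j == i]))
    seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    expect_true(all(seen))
    path <- tempfile(fileext = ".sdf")
    writeLigandSDF(lig, path)
    back <- readLigand(path)
    expect_equal(elements(back), elements(lig))
    expect_equal(paste(bondTable(back)$i, bondTable(back)$j),
                 paste(b$i, b$j))
  }
})

test_that("noiseless datasets obey the planted affinity law exactly", {
  td <- tempfile()
  spec <- synthSpec(nComplexes = 5, noiseSd = 0, seed = 80)
  mf <- generateDataset(spec, td)
  df <- readManifest(mf)
  expect_equal(nrow(df), 5L)
  expect_length(list.files(td, pattern = "\\.(pdb|sdf)$"), 15L)
  for (r in seq_len(nrow(df))) {
    pocket <- readProteinStructure(df$pocket_path[r])
    law <- plantedAffinity(pocket@residues$code)
    expect_equal(df$affinity[r], law, tolerance = 1e-6)
  }
})

test_that("dataset generation is byte-identical under a fixed seed", {
  t1 <- tempfile(); t2 <- tempfile()
  spec <- synthSpec(nComplexes = 4, seed = 81)
  m1 <- generateDataset(spec, t1)
  m2 <- generateDataset(spec, t2)
  expect_identical(readLines(m1), readLines(m2))
  f1 <- sort(basename(list.files(t1)))
  for (f in f1)
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
})

test_that("all generated files parse through the readers with zero skips", {
  td <- tempfile()
  mf <- generateDataset(synthSpec(nComplexes = 6, seed = 82), td)
  df <- readManifest(mf)
  for (r in seq_len(nrow(df))) {
    p <- readProteinStructure(df$protein_path[r])
    expect_equal(skipCount(p), 0L)
    k <- readProteinStructure(df$pocket_path[r])
    expect_equal(skipCount(k), 0L)
    expect_gte(nAtoms(readLigand(df$ligand_path[r])), 1L)
  }
  # and the samples featurize end to end
  samples <- featurizeDataset(df, modelConfig())
  expect_length(samples, 6L)
})

test_that("ordinary least squares on pocket composition recovers the planted weights", {
  td <- tempfile()
  spec <- synthSpec(nComplexes = 120, noiseSd = 0.1, seed = 83)
  mf <- generateDataset(spec, td)
  df <- readManifest(mf)
  vocab <- defaultResidueVocab()
  X <- t(vapply(seq_len(nrow(df)), function(r) {
    codes <- readProteinStructure(df$pocket_path[r])@residues$code
    tabulate(match(codes, vocab), nbins = 20) / length(codes)
  }, numeric(20)))
  colnames(X) <- vocab
  fit <- lm(df$affinity ~ 0 + X)
  est <- coef(fit)
  se <- coef(summary(fit))[, "Std. Error"]
  w <- defaultPlantedWeights()
  expect_true(all(abs(est - w) <= 3 * se))
})
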