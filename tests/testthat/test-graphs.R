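twoResidueStructure <- function(xB) {
  res <- data.frame(chain = "A", resno = 1:2, insert = "",
                    resid = c("ALA", "GLY"), code = c("A", "G"),
                    x = c(0, xB), y = 0, z = 0)
  new("ProteinStructure", id = "t", residues = res, chains = "A",
      nSkipped = 0L)
}

test_that("contact edges respect the 8 A closed cutoff boundary", {
  feats <- diag(2)
  near <- buildResidueGraph(twoResidueStructure(7.9), feats)
  expect_equal(nrow(edgeMatrix(near)), 1L)
  far <- buildResidueGraph(twoResidueStructure(8.1), feats)
  expect_equal(nrow(edgeMatrix(far)), 0L)
  exact <- buildResidueGraph(twoResidueStructure(8.0), feats)
  expect_equal(nrow(edgeMatrix(exact)), 1L)   # closed boundary
})

test_that("single-residue structures give one vertex and no edges", {
  res <- data.frame(chain = "A", resno = 1, insert = "", resid = "ALA",
                    code = "A", x = 0, y = 0, z = 0)
  s <- new("ProteinStructure", id = "t", residues = res, chains = "A",
           nSkipped = 0L)
  g <- buildResidueGraph(s, matrix(1, 1, 4))
  expect_equal(nVertices(g), 1L)
  expect_equal(nrow(edgeMatrix(g)), 0L)
})

test_that("residue graphs match the brute-force all-pairs oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    xyz <- matrix(runif(3 * n, 0, 25), n, 3)
    res <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                      resid = "ALA", code = "A",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    s <- new("ProteinStructure", id = "t", residues = res, chains = "A",
             nSkipped = 0L)
    for (cutoff in c(4, 8, 12)) {
      g <- buildResidueGraph(s, matrix(0, n, 2), cutoff = cutoff)
      oracle <- bruteContactEdges(xyz, cutoff)
      expect_equal(edgeMatrix(g), oracle, ignore_attr = TRUE)
    }
  }
})

test_that("synthetic chains have symmetric adjacency with all consecutive contacts", {
  prot <- generateProtein(35, seed = 5)
  g <- buildResidueGraph(prot, oneHotEncode(prot@residues$code))
  e <- edgeMatrix(g)
  adj <- matrix(FALSE, 35, 35)
  adj[e] <- TRUE
  adj <- adj | t(adj)
  expect_true(isSymmetric(adj))
  # Ca spacing 3.8 A < 8 A: every consecutive pair must be an edge
  expect_true(all(adj[cbind(1:34, 2:35)]))
})

test_that("padded feature rows are sliced off, short features error", {
  prot <- generateProtein(10, seed = 2)
  padded <- rbind(oneHotEncode(prot@residues$code), matrix(0, 5, 20))
  g <- buildResidueGraph(prot, padded)
  expect_equal(nrow(vertexFeatures(g)), 10L)
  expect_error(buildResidueGraph(prot, matrix(0, 4, 20)), "rows")
})

test_that("molecular graphs strip hydrogens with their bonds", {
  mol <- readLigand(fixtureEthanolSDF())
  g <- buildMolecularGraph(mol)
  expect_equal(nVertices(g), 3L)
  expect_equal(nrow(edgeMatrix(g)), 2L)
  expect_equal(dim(vertexFeatures(g)), c(3L, 27L))
  withH <- buildMolecularGraph(mol, includeHydrogens = TRUE)
  expect_equal(nVertices(withH), 9L)
  expect_equal(nrow(edgeMatrix(withH)), 8L)
})

test_that("a benzene-like ring gives 6 vertices and 6 edges", {
  ring <- new("LigandMolecule", id = "benzene",
              atoms = data.frame(element = rep("C", 6),
                                 x = cos(2 * pi * (0:5) / 6) * 1.39,
                                 y = sin(2 * pi * (0:5) / 6) * 1.39, z = 0),
              bonds = data.frame(i = 1:6, j = c(2:6, 1),
                                 order = rep(1L, 6)))
  g <- buildMolecularGraph(ring)
  expect_equal(nVertices(g), 6L)
  expect_equal(nrow(edgeMatrix(g)), 6L)
})

test_that("vertex degree sequence matches an independent bond recount", {
  for (seed in 1:5) {
    lig <- generateLigand(12, seed = seed)
    g <- buildMolecularGraph(lig)
    e <- edgeMatrix(g)
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = nVertices(g))
    b <- bondTable(lig)   # generator emits heavy atoms only
    oracle <- integer(nAtoms(lig))
    for (r in seq_len(nrow(b))) {
      oracle[b$i[r]] <- oracle[b$i[r]] + 1L
      oracle[b$j[r]] <- oracle[b$j[r]] + 1L
    }
    expect_equal(deg, oracle)
    expect_lte(nrow(e), nrow(b))
  }
})

test_that("batching is a reversible block-diagonal union", {
  set.seed(9)
  gs <- lapply(c(2, 3, 5), function(n) {
    prot <- generateProtein(n + 5, seed = n)
    buildResidueGraph(prot, oneHotEncode(prot@residues$code))
  })
  b <- batchGraphs(gs)
  expect_equal(nVertices(b), sum(sapply(gs, nVertices)))
  expect_equal(graphMembership(b),
               rep(1:3, times = sapply(gs, nVertices)))
  back <- unbatchGraphs(b)
  for (k in 1:3) {
    expect_equal(edgeMatrix(back[[k]]), edgeMatrix(gs[[k]]))
    expect_equal(vertexFeatures(back[[k]]), vertexFeatures(gs[[k]]))
  }
  single <- unbatchGraphs(batchGraphs(gs[2]))[[1]]
  expect_equal(edgeMatrix(single), edgeMatrix(gs[[2]]))
  # membership [0-based in spec] maps to 1-based graph indices here
  two <- batchGraphs(gs[1:2])
  expect_equal(graphMembership(two), c(rep(1L, nVertices(gs[[1]])),
                                       rep(2L, nVertices(gs[[2]]))))
  bad <- new("SimpleGraph", nVertices = 1L,
             edges = matrix(integer(), ncol = 2),
             features = matrix(0, 1, 5), labels = character())
  expect_error(batchGraphs(list(gs[[1]], bad)), "mixed|dimension")
})

test_that("graph archives round-trip through JSON", {
  prot <- generateProtein(12, seed = 4)
  g <- buildResidueGraph(prot, oneHotEncode(prot@residues$code))
  path <- tempfile(fileext = ".json")
  writeGraphArchive(g, path)
  back <- readGraphArchive(path)
  expect_equal(nVertices(back), nVertices(g))
  expect_equal(edgeMatrix(back), edgeMatrix(g), ignore_attr = TRUE)
  expect_equal(vertexFeatures(back), vertexFeatures(g), ignore_attr = TRUE)
})
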