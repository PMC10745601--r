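test_that("PDB C-alpha extraction keeps file order and ignores hetero records", {
  p <- readProteinStructure(fixturePDB())
  expect_equal(proteinSequence(p), "AGV")
  expect_equal(nResidues(p), 3L)
  expect_equal(skipCount(p), 0L)
  expect_equal(unname(caCoords(p)[, 1]), c(1.0, 4.8, 8.6))
  # deterministic: identical file -> identical structure
  p2 <- readProteinStructure(fixturePDB())
  expect_equal(p@residues, p2@residues)
})

test_that("residues without a C-alpha are skipped and counted", {
  path <- writeTempFile(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   GLY A   2       1.000   0.000   0.000  1.00  0.00           N",
    "ATOM      3  CA  VAL A   3       3.800   0.000   0.000  1.00  0.00           C",
    "END"), ".pdb")
  p <- readProteinStructure(path)
  expect_equal(nResidues(p), 2L)
  expect_equal(skipCount(p), 1L)
  expect_equal(proteinSequence(p), "AV")
})

test_that("nonstandard residues map to one-letter code X", {
  path <- writeTempFile(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  MSE A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), ".pdb")
  p <- readProteinStructure(path)
  expect_equal(proteinSequence(p), "AX")
})

test_that("unreadable and C-alpha-free PDB files raise errors", {
  expect_error(readProteinStructure(tempfile()), "cannot read")
  noCA <- writeTempFile(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), ".pdb")
  expect_error(readProteinStructure(noCA), "C-alpha")
})

test_that("SDF ligand parsing preserves atoms, bonds and coordinates", {
  m <- readLigand(fixtureEthanolSDF())
  expect_equal(nAtoms(m), 9L)
  expect_equal(nrow(bondTable(m)), 8L)
  expect_equal(elements(m)[1:3], c("C", "C", "O"))
  expect_equal(m@atoms$x[3], 1.561)
  expect_true(all(bondTable(m)$i < bondTable(m)$j))
})

test_that("MOL2 parsing agrees with SDF for the same molecule", {
  sdf <- readLigand(fixtureEthanolSDF())
  mol2 <- readLigand(fixtureEthanolMOL2())
  expect_equal(sort(elements(mol2)), sort(elements(sdf)))
  expect_equal(nrow(bondTable(mol2)), nrow(bondTable(sdf)))
  key <- function(m) paste(bondTable(m)$i, bondTable(m)$j)
  expect_setequal(key(mol2), key(sdf))
})

test_that("inconsistent SDF counts line raises a parse error naming the line", {
  bad <- writeTempFile(c(
    "broken", "", "",
    "  5  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.5000    0.0000    0.0000 C   0  0",
    "    3.0000    0.0000    0.0000 O   0  0",
    "    4.5000    0.0000    0.0000 N   0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END", "$$$$"), ".sdf")
  expect_error(readLigand(bad), "counts line")
})

test_that("PSSM parsing returns scores as given", {
  path <- writeTempFile(c(
    "",
    "Last position-specific scoring matrix computed",
    "            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V",
    paste("    1 M   -1  -2  -3  -4   5   0  -2   1   2   3  -3   0   7  -1  -2   0   1  -4  -3   2",
          " 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.5 0.1"),
    paste("    2 K    4   3   2   1   0  -1  -2  -3  -4   5   6  -6   0   1   2   3  -3   0   1  -2",
          " 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0  0.5 0.1")), ".pssm")
  pf <- parseProfile(path, "PSSM")
  m <- profileMatrix(pf)
  expect_equal(dim(m), c(2L, 20L))
  expect_equal(unname(m[1, 1:5]), c(-1, -2, -3, -4, 5))
  expect_equal(unname(m[2, 20]), -2)
})

test_that("HHM emission codes convert to probabilities, '*' to zero", {
  codes1 <- paste(rep("*", 20), collapse = "\t")
  codes2 <- paste(rep("1000", 20), collapse = "\t")
  path <- writeTempFile(c(
    "HHsearch 1.5", "NAME  test", "LENG  2",
    "HMM    A\tC\tD\tE\tF\tG\tH\tI\tK\tL\tM\tN\tP\tQ\tR\tS\tT\tV\tW\tY",
    "       M->M M->I M->D I->M I->I D->M D->D Neff",
    "       0 * * * * * * *",
    paste0("A 1\t", codes1, "\t1"),
    "       100 * * * * * * *",
    paste0("K 2\t", codes2, "\t2"),
    "       100 * * * * * * *",
    "//"), ".hhm")
  pf <- parseProfile(path, "HMM")
  m <- profileMatrix(pf)
  expect_equal(dim(m), c(2L, 20L))
  expect_equal(unname(m[1, ]), rep(0, 20))
  # 2^(-1000/1000) = 0.5, computed by hand
  expect_equal(unname(m[2, ]), rep(0.5, 20))
})

test_that("manifest reading validates schema and affinities", {
  good <- writeTempFile(c(
    "complex_id,protein_path,pocket_path,ligand_path,affinity",
    "c1,/a/p1.pdb,/a/k1.pdb,/a/l1.sdf,5.5",
    "c2,/a/p2.pdb,/a/k2.pdb,/a/l2.sdf,7.25"), ".csv")
  df <- readManifest(good)
  expect_equal(df$complex_id, c("c1", "c2"))
  expect_equal(df$affinity, c(5.5, 7.25))

  empty <- writeTempFile(
    "complex_id,protein_path,pocket_path,ligand_path,affinity", ".csv")
  expect_equal(nrow(readManifest(empty)), 0L)

  bad <- writeTempFile(c(
    "complex_id,protein_path,pocket_path,ligand_path,affinity",
    "c1,/a,/a,/a,5.5", "c2,/a,/a,/a,6.5", "c3,/a,/a,/a,abc"), ".csv")
  expect_error(readManifest(bad), "row 3")

  noCol <- writeTempFile(c("complex_id,protein_path,affinity",
                           "c1,/a,5.5"), ".csv")
  expect_error(readManifest(noCol), "missing column")
})

test_that("prediction tables round-trip to 1e-6 and support empty input", {
  df <- data.frame(complex_id = c("a", "b"),
                   y_true = c(5.123456789, 6.5),
                   y_pred = c(5.2, 6.987654321))
  path <- tempfile(fileext = ".csv")
  writePredictions(df, path)
  back <- readPredictions(path)
  expect_equal(back$y_true, df$y_true, tolerance = 1e-6)
  expect_equal(back$y_pred, df$y_pred, tolerance = 1e-6)
  expect_equal(back$complex_id, df$complex_id)

  writePredictions(df[0, ], path)
  expect_equal(length(readLines(path)), 1L)   # header only
  expect_equal(nrow(readPredictions(path)), 0L)

  expect_error(writePredictions(data.frame(complex_id = "a", y_true = NaN,
                                           y_pred = 1), path), "finite")
})

test_that("pocket files subset their protein with exactly matching coordinates", {
  prot <- generateProtein(40, seed = 42)
  pPath <- tempfile(fileext = ".pdb")
  kPath <- tempfile(fileext = ".pdb")
  writeProteinPDB(prot, pPath)
  writeProteinPDB(prot, kPath, residueIndex = 11:20)
  full <- readProteinStructure(pPath)
  pocket <- readProteinStructure(kPath)
  idx <- match(paste(pocket@residues$chain, pocket@residues$resno),
               paste(full@residues$chain, full@residues$resno))
  expect_false(anyNA(idx))
  expect_identical(caCoords(pocket), caCoords(full)[idx, , drop = FALSE])
})
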