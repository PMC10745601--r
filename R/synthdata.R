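# Seeded generator of synthetic protein-pocket-ligand complexes with a
# planted affinity law. Proteins are C-alpha traces laid out as 3D
# self-avoiding random walks with the canonical 3.8 A virtual bond length;
# ligands are random connected heavy-atom graphs written as SDF V2000.
# The planted law ties the affinity to the pocket's residue composition, so
# that pocket knowledge is, by construction, what drives the label.

#' Synthetic dataset specification
#'
#' Defaults are desk-scale study conditions: 250 complexes, 30-60 residues,
#' pockets of 8-15 contiguous residues, 6-15 heavy atoms, C-alpha step
#' 3.8 A with 3.5 A non-consecutive clearance, label noise 0.2 pKd units.
#' The planted weights assign each residue type a value on a realistic pKd
#' scale (2 to 11, alphabetical one-letter order); the affinity of a complex
#' is the mean planted weight of its pocket residues plus Gaussian noise.
#'
#' @param nComplexes number of complexes.
#' @param residueRange min/max protein length.
#' @param pocketRange min/max pocket size (contiguous residue window).
#' @param atomRange min/max ligand heavy atoms.
#' @param stepA consecutive C-alpha distance in Angstrom.
#' @param clearanceA minimum non-consecutive C-alpha distance.
#' @param noiseSd standard deviation of the Gaussian label noise (pKd).
#' @param plantedWeights named numeric vector: residue type -> pKd weight.
#' @param seed integer seed.
#' @return a \code{SynthSpec} object.
#' @export
synthSpec <- function(nComplexes = 250, residueRange = c(30, 60),
                      pocketRange = c(8, 15), atomRange = c(6, 15),
                      stepA = 3.8, clearanceA = 3.5, noiseSd = 0.2,
                      plantedWeights = defaultPlantedWeights(), seed = 1) {
  new("SynthSpec", nComplexes = as.numeric(nComplexes),
      residueRange = as.numeric(residueRange),
      pocketRange = as.numeric(pocketRange),
      atomRange = as.numeric(atomRange), stepA = stepA,
      clearanceA = clearanceA, noiseSd = noiseSd,
      plantedWeights = plantedWeights, seed = as.numeric(seed))
}

#' @rdname synthSpec
#' @export
defaultPlantedWeights <- function() {
  setNames(seq(2, 11, length.out = 20), defaultResidueVocab())
}

#' @exportClass SynthSpec
setClass("SynthSpec",
  slots = c(nComplexes = "numeric", residueRange = "numeric",
            pocketRange = "numeric", atomRange = "numeric",
            stepA = "numeric", clearanceA = "numeric", noiseSd = "numeric",
            plantedWeights = "numeric", seed = "numeric"))

setValidity("SynthSpec", function(object) {
  if (object@nComplexes < 1) return("nComplexes must be >= 1")
  if (diff(object@residueRange) < 0 || diff(object@pocketRange) < 0 ||
      diff(object@atomRange) < 0) return("ranges must be nonempty (min <= max)")
  if (object@pocketRange[2] > object@residueRange[1])
    return("pocket size must not exceed the minimum protein length")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!all(defaultResidueVocab() %in% names(object@plantedWeights)))
    return("plantedWeights must cover all 20 residue types")
  TRUE
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(
    "SynthSpec: %d complexes, %d-%d residues (pocket %d-%d), %d-%d heavy atoms, noise %.2f, seed %d\n",
    object@nComplexes, object@residueRange[1], object@residueRange[2],
    object@pocketRange[1], object@pocketRange[2], object@atomRange[1],
    object@atomRange[2], object@noiseSd, object@seed))
})

#' Generate a synthetic protein C-alpha trace
#'
#' A 3D self-avoiding random walk: every consecutive C-alpha pair is exactly
#' \code{stepA} apart and every non-consecutive pair at least
#' \code{clearanceA} apart; the sequence is a uniform draw over the 20
#' standard residues. Draws from the global RNG unless \code{seed} is given.
#'
#' @param nResidues chain length (>= 2).
#' @param stepA,clearanceA geometry in Angstrom.
#' @param seed optional seed.
#' @param id structure identifier.
#' @return a \linkS4class{ProteinStructure}.
#' @export
generateProtein <- function(nResidues, stepA = 3.8, clearanceA = 3.5,
                            seed = NULL, id = "synthetic") {
  if (nResidues < 2) stop("nResidues must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in 1:25) {
    xyz <- matrix(NA_real_, nResidues, 3)
    xyz[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:nResidues) {
      placed <- FALSE
      for (try in 1:100) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- xyz[i - 1, ] + stepA * u
        if (i > 2) {
          dd <- sqrt(rowSums(sweep(xyz[1:(i - 2), , drop = FALSE], 2, cand,
                                   "-")^2))
          if (any(dd < clearanceA)) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      codes <- sample(defaultResidueVocab(), nResidues, replace = TRUE)
      res <- data.frame(chain = "A", resno = seq_len(nResidues),
                        insert = "", resid = unname(.AA1TO3[codes]),
                        code = codes,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
      return(new("ProteinStructure", id = id, residues = res, chains = "A",
                 nSkipped = 0L))
    }
  }
  stop("self-avoiding walk placement failed after bounded retries; re-seed")
}

#' Write a C-alpha trace as a fixed-column PDB file
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output path.
#' @param residueIndex optional subset of residue indices to write (used for
#'   pocket files); records keep their original residue numbers.
#' @export
writeProteinPDB <- function(structure, path, residueIndex = NULL) {
  r <- structure@residues
  if (!is.null(residueIndex)) r <- r[residueIndex, , drop = FALSE]
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(r)), r$resid, r$chain, r$resno,
    ifelse(r$insert == "", " ", r$insert), r$x, r$y, r$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a synthetic ligand
#'
#' A random spanning tree over the heavy atoms plus up to two extra
#' ring-closing bonds (always connected); elements drawn from C/N/O/S with
#' fixed probabilities (0.6/0.15/0.15/0.1); coordinates by layered placement
#' at ~1.5 A bond length.
#'
#' @param nHeavyAtoms atom count (>= 1).
#' @param seed optional seed.
#' @param id molecule identifier.
#' @return a \linkS4class{LigandMolecule}.
#' @export
generateLigand <- function(nHeavyAtoms, seed = NULL, id = "synthetic") {
  if (nHeavyAtoms < 1) stop("nHeavyAtoms must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  el <- sample(c("C", "N", "O", "S"), nHeavyAtoms, replace = TRUE,
               prob = c(0.6, 0.15, 0.15, 0.1))
  xyz <- matrix(0, nHeavyAtoms, 3)
  bonds <- NULL
  if (nHeavyAtoms > 1) {
    parent <- c(NA_integer_,
                vapply(2:nHeavyAtoms,
                       function(i) sample.int(i - 1L, 1L), integer(1)))
    for (i in 2:nHeavyAtoms) {
      for (try in 1:50) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- xyz[parent[i], ] + 1.5 * u
        dd <- sqrt(rowSums(sweep(xyz[1:(i - 1), , drop = FALSE], 2, cand,
                                 "-")^2))
        if (all(dd > 1.0) || try == 50) { xyz[i, ] <- cand; break }
      }
    }
    bonds <- data.frame(i = pmin(2:nHeavyAtoms, parent[-1]),
                        j = pmax(2:nHeavyAtoms, parent[-1]), order = 1L)
    # ring closures among non-bonded pairs
    if (nHeavyAtoms >= 4) {
      all_pairs <- which(upper.tri(matrix(0, nHeavyAtoms, nHeavyAtoms)),
                         arr.ind = TRUE)
      key <- paste(all_pairs[, 1], all_pairs[, 2])
      free <- which(!key %in% paste(bonds$i, bonds$j))
      nExtra <- min(sample(0:2, 1), length(free))
      if (nExtra > 0) {
        pick <- free[sample.int(length(free), nExtra)]
        bonds <- rbind(bonds,
                       data.frame(i = all_pairs[pick, 1],
                                  j = all_pairs[pick, 2], order = 1L))
      }
    }
    row.names(bonds) <- NULL
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  new("LigandMolecule", id = id,
      atoms = data.frame(element = el, x = round(xyz[, 1], 4),
                         y = round(xyz[, 2], 4), z = round(xyz[, 3], 4),
                         stringsAsFactors = FALSE),
      bonds = bonds)
}

#' Write a ligand as SDF V2000
#'
#' @param mol a \linkS4class{LigandMolecule}.
#' @param path output path.
#' @export
writeLigandSDF <- function(mol, path) {
  a <- mol@atoms; b <- mol@bonds
  header <- c(mol@id, "  StructDTA synthetic", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atomLines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element)
  bondLines <- if (nrow(b)) sprintf("%3d%3d%3d  0", b$i, b$j, b$order)
               else character()
  writeLines(c(header, counts, atomLines, bondLines, "M  END", "$$$$"),
             path)
  invisible(path)
}

#' Planted affinity of a pocket
#'
#' Mean planted weight of the pocket's residue types (the noiseless planted
#' law).
#'
#' @param codes one-letter residue codes of the pocket.
#' @param weights named planted-weight vector.
#' @return noiseless pKd.
#' @export
plantedAffinity <- function(codes, weights = defaultPlantedWeights()) {
  mean(weights[codes])
}

#' Generate a synthetic dataset on disk
#'
#' Per complex: a protein PDB, a pocket PDB (a contiguous seeded residue
#' window of the protein) and a ligand SDF, plus a manifest CSV. The
#' affinity is the mean planted weight over the pocket residues plus
#' Gaussian noise of sd \code{noiseSd}. Fully reproducible from
#' (spec, seed).
#'
#' @param spec a \code{SynthSpec}.
#' @param outDir output directory (created if needed).
#' @return the manifest path.
#' @export
generateDataset <- function(spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  set.seed(spec@seed)
  n <- spec@nComplexes
  rows <- vector("list", n)
  for (c in seq_len(n)) {
    id <- sprintf("cplx_%04d", c)
    nres <- sample(spec@residueRange[1]:spec@residueRange[2], 1)
    psize <- sample(spec@pocketRange[1]:spec@pocketRange[2], 1)
    natoms <- sample(spec@atomRange[1]:spec@atomRange[2], 1)
    prot <- generateProtein(nres, spec@stepA, spec@clearanceA, id = id)
    pstart <- sample(seq_len(nres - psize + 1L), 1)
    pocketIdx <- pstart:(pstart + psize - 1L)
    lig <- generateLigand(natoms, id = id)
    aff <- plantedAffinity(prot@residues$code[pocketIdx],
                           spec@plantedWeights) +
           rnorm(1, 0, spec@noiseSd)
    pPath <- file.path(outDir, paste0(id, "_protein.pdb"))
    kPath <- file.path(outDir, paste0(id, "_pocket.pdb"))
    lPath <- file.path(outDir, paste0(id, "_ligand.sdf"))
    writeProteinPDB(prot, pPath)
    writeProteinPDB(prot, kPath, residueIndex = pocketIdx)
    writeLigandSDF(lig, lPath)
    rows[[c]] <- data.frame(complex_id = id,
                            protein_path = basename(pPath),
                            pocket_path = basename(kPath),
                            ligand_path = basename(lPath),
                            affinity = sprintf("%.6f", aff))
  }
  manifest <- file.path(outDir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
            quote = FALSE)
  manifest
}
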