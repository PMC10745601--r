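# Attention-based interpretability: per-atom residue rankings, per-residue
# atom rankings, pocket-hit fractions and atom-coverage statistics.

#' Top-k indices per row of a score matrix
#'
#' For each row, the indices of the k largest entries in descending score
#' order, ties broken by ascending index (deterministic). k larger than the
#' row length returns all indices.
#'
#' @param scoreMatrix numeric matrix.
#' @param k number of picks per row.
#' @return list of integer index vectors (1-based), one per row.
#' @export
topKRows <- function(scoreMatrix, k) {
  if (!is.matrix(scoreMatrix) || !nrow(scoreMatrix) || !ncol(scoreMatrix))
    stop("scoreMatrix must be a nonempty matrix")
  if (k < 1) stop("k must be >= 1")
  kk <- min(k, ncol(scoreMatrix))
  lapply(seq_len(nrow(scoreMatrix)), function(r) {
    row <- scoreMatrix[r, ]
    order(-row, seq_along(row))[seq_len(kk)]
  })
}

#' Fraction of top-k picks that land in the pocket
#'
#' Counts every (row, picked index) pair with a TRUE mask entry and divides
#' by the total number of picks.
#'
#' @param topIndices list of index vectors (from \code{\link{topKRows}}).
#' @param mask logical pocket mask over the indexed positions.
#' @return fraction in [0, 1].
#' @export
pocketHitFraction <- function(topIndices, mask) {
  idx <- unlist(topIndices, use.names = FALSE)
  if (!length(idx)) stop("no picks")
  if (any(idx < 1 | idx > length(mask))) stop("pick index out of mask range")
  mean(mask[idx])
}

#' Interpret one complex through its attention matrices
#'
#' Runs the model with attention, then reports, for each k in \code{kRes},
#' the fraction of per-atom top-k residues that lie in the pocket
#' (atoms-to-residues direction) and, for each k in \code{kAtom}, the
#' fraction of distinct heavy atoms picked in any per-residue top-k list
#' (residues-to-atoms direction, coverage of the drug's heavy atoms).
#'
#' @param sample a featurized \linkS4class{ComplexSample} (hydrogens are
#'   already absent from the drug graph).
#' @param params trained model parameters.
#' @param config the matching \code{ModelConfig}.
#' @param kRes residue-side k values (default 5, 10, 20).
#' @param kAtom atom-side k values (default 3, 5, 8).
#' @return list with \code{id}, \code{residueHits} (named fractions),
#'   \code{atomCoverage} (named fractions), \code{topResidues} /
#'   \code{topAtoms} (per-k lists of per-row index lists), \code{nResidues},
#'   \code{nAtoms}, \code{pocketSize}.
#' @export
interpretComplex <- function(sample, params, config = modelConfig(),
                             kRes = c(5, 10, 20), kAtom = c(3, 5, 8)) {
  mask <- pocketMask(sample)
  if (!any(mask)) stop("complex has no pocket residues")
  fw <- forwardComplex(sample, params, config, attention = TRUE)
  att <- fw$attention
  a2r <- atomsToResidues(att)
  r2a <- residuesToAtoms(att)
  residueHits <- vapply(kRes, function(k)
    pocketHitFraction(topKRows(a2r, k), mask), numeric(1))
  names(residueHits) <- paste0("top", kRes)
  topResidues <- lapply(kRes, function(k) topKRows(a2r, k))
  names(topResidues) <- paste0("top", kRes)
  atomCoverage <- vapply(kAtom, function(k) {
    picked <- unique(unlist(topKRows(r2a, k)))
    length(picked) / ncol(r2a)
  }, numeric(1))
  names(atomCoverage) <- paste0("top", kAtom)
  topAtoms <- lapply(kAtom, function(k) topKRows(r2a, k))
  names(topAtoms) <- paste0("top", kAtom)
  list(id = sample@id, residueHits = residueHits,
       atomCoverage = atomCoverage, topResidues = topResidues,
       topAtoms = topAtoms, nResidues = ncol(a2r), nAtoms = nrow(a2r),
       pocketSize = sum(mask), prediction = fw$prediction)
}

#' Aggregate interpretability statistics over a dataset
#'
#' Residue-side fractions are reported two ways: pooled over every
#' (atom, pick) pair in the dataset, and as the unweighted mean of
#' per-complex fractions.
#'
#' @param samples list of featurized complexes.
#' @param params,config trained parameters and their configuration.
#' @param kRes,kAtom k values as in \code{\link{interpretComplex}}.
#' @return list with \code{perComplex} (list of reports),
#'   \code{residueHitsPooled}, \code{residueHitsMean},
#'   \code{atomCoverageMean}.
#' @export
interpretDataset <- function(samples, params, config = modelConfig(),
                             kRes = c(5, 10, 20), kAtom = c(3, 5, 8)) {
  reports <- lapply(samples, interpretComplex, params = params,
                    config = config, kRes = kRes, kAtom = kAtom)
  hitMat <- do.call(rbind, lapply(reports, `[[`, "residueHits"))
  covMat <- do.call(rbind, lapply(reports, `[[`, "atomCoverage"))
  # pooled = picks-weighted mean; per-atom pick count is nAtoms * k capped
  # at nResidues
  nAtomsV <- vapply(reports, `[[`, numeric(1), "nAtoms")
  nResV <- vapply(reports, `[[`, numeric(1), "nResidues")
  pooled <- vapply(seq_along(kRes), function(j) {
    picks <- nAtomsV * pmin(kRes[j], nResV)
    sum(hitMat[, j] * picks) / sum(picks)
  }, numeric(1))
  names(pooled) <- colnames(hitMat)
  list(perComplex = reports,
       residueHitsPooled = pooled,
       residueHitsMean = colMeans(hitMat),
       atomCoverageMean = colMeans(covMat))
}

#' Export attention selections for molecular viewers
#'
#' Writes plain-text identifier lists per complex: the pocket-annotated
#' top-k residues for each atom and top-k atoms for each residue, one line
#' per pick, consumable by external viewers.
#'
#' @param report result of \code{\link{interpretComplex}}.
#' @param sample the matching \linkS4class{ComplexSample}.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
exportSelections <- function(report, sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  resLabels <- vertexLabels(sample@targetGraph)
  atomLabels <- vertexLabels(sample@drug)
  mask <- pocketMask(sample)
  paths <- character()
  for (kn in names(report$topResidues)) {
    f <- file.path(dir, paste0(report$id, "_residues_", kn, ".txt"))
    picks <- report$topResidues[[kn]]
    lines <- unlist(lapply(seq_along(picks), function(a)
      sprintf("%s\t%s\t%s", atomLabels[a], resLabels[picks[[a]]],
              ifelse(mask[picks[[a]]], "pocket", "outside"))))
    writeLines(lines, f)
    paths <- c(paths, f)
  }
  for (kn in names(report$topAtoms)) {
    f <- file.path(dir, paste0(report$id, "_atoms_", kn, ".txt"))
    picks <- report$topAtoms[[kn]]
    lines <- unlist(lapply(seq_along(picks), function(r)
      sprintf("%s\t%s", resLabels[r],
              paste(atomLabels[picks[[r]]], collapse = ","))))
    writeLines(lines, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
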