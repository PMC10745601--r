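# Turn manifest rows into featurized ComplexSample objects: parse the
# files, match pocket residues to target residues, build the three graphs
# and precompute the unrolled convolution inputs.

.matchPocket <- function(protein, pocket, id, coordTol = 1e-3) {
  pk <- paste(protein@residues$chain, protein@residues$resno,
              protein@residues$insert, sep = "|")
  qk <- paste(pocket@residues$chain, pocket@residues$resno,
              pocket@residues$insert, sep = "|")
  idx <- match(qk, pk)
  if (anyNA(idx))
    stop("complex '", id, "': ", sum(is.na(idx)),
         " pocket residue(s) not found in the target structure ",
         "(matching by chain/residue number/insertion code)")
  # coordinates are a cross-check only, never the matching key
  dd <- sqrt(rowSums((caCoords(pocket) -
                      caCoords(protein)[idx, , drop = FALSE])^2))
  if (any(dd > coordTol))
    warning("complex '", id, "': pocket C-alpha coordinates deviate from ",
            "the target structure by up to ", signif(max(dd), 3), " A")
  sort(unique(idx))
}

#' Featurize one complex
#'
#' Reads the protein, pocket and ligand files of a manifest row, matches
#' pocket residues to target residues by (chain, residue number, insertion
#' code), builds the residue contact graphs (target and pocket; pocket edges
#' are computed within the pocket residue set) and the heavy-atom molecular
#' graph, one-hot vertex features throughout, and caches the unrolled
#' convolution inputs for the configured kernels.
#'
#' @param entry one manifest row (list or single-row data.frame with
#'   complex_id, protein_path, pocket_path, ligand_path, affinity).
#' @param config a \code{ModelConfig}.
#' @return a \linkS4class{ComplexSample}.
#' @export
featurizeComplex <- function(entry, config = modelConfig()) {
  id <- as.character(entry$complex_id)
  protein <- readProteinStructure(entry$protein_path, id = id)
  pocket <- readProteinStructure(entry$pocket_path,
                                 id = paste0(id, "_pocket"))
  ligand <- readLigand(entry$ligand_path, id = id)
  pocketIndex <- .matchPocket(protein, pocket, id)
  rv <- config@residueVocab
  targetFeat <- oneHotEncode(protein@residues$code, rv)
  targetGraph <- buildResidueGraph(protein, targetFeat,
                                   cutoff = config@contactCutoff)
  pocketStruct <- new("ProteinStructure", id = pocket@id,
                      residues = protein@residues[pocketIndex, ,
                                                  drop = FALSE],
                      chains = unique(protein@residues$chain[pocketIndex]),
                      nSkipped = pocket@nSkipped)
  pocketFeat <- oneHotEncode(pocketStruct@residues$code, rv)
  pocketGraph <- buildResidueGraph(pocketStruct, pocketFeat,
                                   cutoff = config@contactCutoff)
  drug <- buildMolecularGraph(ligand, config@atomVocab,
                              includeHydrogens = FALSE)
  sample <- new("ComplexSample", id = id,
                affinity = as.numeric(entry$affinity),
                protein = protein, pocketIndex = pocketIndex,
                drug = drug, targetGraph = targetGraph,
                pocketGraph = pocketGraph, cache = list())
  sample@cache <- .cacheSeqInputs(sample, config)
  sample
}

#' Featurize a whole manifest
#'
#' @param manifest manifest data.frame from \code{\link{readManifest}} (or a
#'   path to one).
#' @param config a \code{ModelConfig}.
#' @param verbose print progress.
#' @return list of \linkS4class{ComplexSample}.
#' @export
featurizeDataset <- function(manifest, config = modelConfig(),
                             verbose = FALSE) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  out <- vector("list", nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    out[[r]] <- featurizeComplex(manifest[r, ], config)
    if (verbose && r %% 50 == 0)
      message("featurized ", r, "/", nrow(manifest))
  }
  names(out) <- manifest$complex_id
  out
}
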