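# Readers and writers for the external formats: PDB protein/pocket
# structures (via bio3d), SDF V2000 (via ChemmineR) and TRIPOS MOL2 (via
# bio3d) ligands, PSI-BLAST ASCII PSSM and HHsuite .hhm profiles, and the
# CSV manifest / prediction tables.

#' Read a protein (or pocket) structure from a PDB file
#'
#' Extracts the C-alpha trace: one residue per (chain, residue number,
#' insertion code) group of ATOM records, in file order. Only the first
#' model of multi-model files is used; HETATM and water records are
#' ignored; alternate locations other than ' ' or 'A' are dropped.
#' Residues without a C-alpha atom are skipped and counted in
#' \code{skipCount}. Nonstandard residues get one-letter code \code{"X"}.
#'
#' @param path PDB file path.
#' @param id identifier stored on the object (default: file base name).
#' @return a \linkS4class{ProteinStructure}.
#' @export
readProteinStructure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", " ", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records with C-alpha in '", path, "'")
  ins <- ifelse(is.na(at$insert), "", at$insert)
  rkey <- paste(at$chain, at$resno, ins, sep = "|")
  # residues in order of first appearance
  first <- !duplicated(rkey)
  order_keys <- rkey[first]
  isCA <- at$elety == "CA"
  ca <- at[isCA, , drop = FALSE]
  cakey <- rkey[isCA]
  ca <- ca[!duplicated(cakey), , drop = FALSE]
  cakey <- cakey[!duplicated(cakey)]
  keep <- match(order_keys, cakey)
  skipped <- sum(is.na(keep))
  keep <- keep[!is.na(keep)]
  if (length(keep) == 0L)
    stop("no residues with a C-alpha atom in '", path, "'")
  ca <- ca[keep, , drop = FALSE]
  code <- unname(.AA3TO1[ca$resid])
  code[is.na(code)] <- "X"
  res <- data.frame(
    chain = ifelse(is.na(ca$chain), "", ca$chain),
    resno = as.integer(ca$resno),
    insert = ifelse(is.na(ca$insert), "", ca$insert),
    resid = ca$resid, code = code,
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  new("ProteinStructure", id = id, residues = res,
      chains = unique(res$chain), nSkipped = as.integer(skipped))
}

# strict counts-line check for SDF V2000 before delegating to ChemmineR,
# which silently tolerates inconsistent counts lines
.checkSdfCounts <- function(lines, path) {
  if (length(lines) < 4L) stop("SDF file '", path, "' too short")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop("unparseable SDF counts line (line 4): '", counts, "'")
  body <- lines[-(1:4)]
  endAtoms <- natoms
  endBonds <- natoms + nbonds
  if (length(body) < endBonds)
    stop("SDF counts line declares ", natoms, " atoms / ", nbonds,
         " bonds but the file ends early (line 4: '", counts, "')")
  atomLines <- body[seq_len(endAtoms)]
  bondLines <- if (nbonds) body[(endAtoms + 1L):endBonds] else character()
  badAtom <- which(!grepl("^\\s*-?[0-9.]+\\s+-?[0-9.]+\\s+-?[0-9.]+\\s+[A-Za-z]",
                          atomLines))
  if (length(badAtom))
    stop("SDF counts line declares ", natoms,
         " atoms but the atom block is inconsistent at line ",
         4L + badAtom[1], " of '", path, "'")
  badBond <- which(!grepl("^\\s*[0-9]+\\s*[0-9]+", bondLines))
  if (length(badBond))
    stop("SDF counts line declares ", nbonds,
         " bonds but the bond block is inconsistent at line ",
         4L + natoms + badBond[1], " of '", path, "'")
  invisible(list(natoms = natoms, nbonds = nbonds))
}

.readLigandSdf <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  .checkSdfCounts(lines, path)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- data.frame(
    element = sub("_.*$", "", rownames(ab)),
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    stringsAsFactors = FALSE, row.names = NULL)
  bonds <- if (nrow(bb)) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]), row.names = NULL)
  } else data.frame(i = integer(), j = integer(), order = integer())
  list(atoms = atoms, bonds = bonds)
}

.readLigandMol2 <- function(path, id) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("failed to parse MOL2 file '", path,
                                         "': ", conditionMessage(e)))
  # SYBYL atom types like "C.3", "N.ar" -> element before the dot
  el <- sub("\\..*$", "", m$atom$elety)
  atoms <- data.frame(element = el, x = m$atom$x, y = m$atom$y, z = m$atom$z,
                      stringsAsFactors = FALSE, row.names = NULL)
  b <- m$bond
  ord <- suppressWarnings(as.integer(b$type))
  ord[is.na(ord)] <- 1L   # 'ar'/'am' kept as single bonds; no perception
  bonds <- data.frame(i = as.integer(b$origin), j = as.integer(b$target),
                      order = ord, row.names = NULL)
  list(atoms = atoms, bonds = bonds)
}

#' Read a ligand from an SDF (V2000) or MOL2 (TRIPOS) file
#'
#' Atom order and 3D coordinates are preserved; the bond list is returned
#' as written (undirected, deduplicated, \code{i < j}). Aromatic/amide MOL2
#' bond types are kept as order 1: no bond-order perception beyond the file.
#'
#' @param path ligand file path.
#' @param format \code{"auto"} (by extension), \code{"sdf"} or \code{"mol2"}.
#' @param id identifier (default: file base name).
#' @return a \linkS4class{LigandMolecule}.
#' @export
readLigand <- function(path, format = c("auto", "sdf", "mol2"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read ligand file: ", path)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", mol2 = "mol2",
                     stop("cannot infer ligand format from extension '.",
                          ext, "'; pass format="))
  }
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  parsed <- switch(format, sdf = .readLigandSdf(path, id),
                   mol2 = .readLigandMol2(path, id))
  b <- parsed$bonds
  if (nrow(b)) {
    ii <- pmin(b$i, b$j); jj <- pmax(b$i, b$j)
    b <- data.frame(i = ii, j = jj, order = b$order)
    b <- b[!duplicated(paste(b$i, b$j)), , drop = FALSE]
    row.names(b) <- NULL
  }
  new("LigandMolecule", id = id, atoms = parsed$atoms, bonds = b)
}

#' Parse a sequence profile (PSI-BLAST PSSM or HHsuite .hhm)
#'
#' PSSM: the first 20 score columns of the PSI-BLAST ASCII matrix, returned
#' as given. HHM: the 20 match-emission columns of an HHsuite model; integer
#' codes v are converted to probabilities \code{2^(-v/1000)} and \code{"*"}
#' becomes 0.
#'
#' @param path profile file path.
#' @param kind \code{"PSSM"} or \code{"HMM"}.
#' @return a \linkS4class{ProfileFeatures}.
#' @export
parseProfile <- function(path, kind = c("PSSM", "HMM")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read profile file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (kind == "PSSM") {
    # data rows: position, residue letter, then >= 20 integer scores
    dat <- grep("^\\s*[0-9]+\\s+[A-Z]\\s+-?[0-9]", lines, value = TRUE)
    if (!length(dat)) stop("no PSSM data rows found in '", path, "'")
    rows <- lapply(dat, function(l) {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      sc <- suppressWarnings(as.numeric(tok[-(1:2)]))
      if (length(sc) < 20 || anyNA(sc[1:20]))
        stop("PSSM row with fewer than 20 score columns in '", path, "'")
      sc[1:20]
    })
    m <- do.call(rbind, rows)
  } else {
    start <- grep("^HMM\\s", lines)
    if (!length(start)) stop("no 'HMM' header found in '", path, "'")
    body <- lines[(start[1] + 3L):length(lines)]   # header + transition label + NULL row
    # match-state rows: "A 12  <20 fields>  5" (residue letter + position)
    isMatch <- grepl("^[A-Z]\\s+[0-9]+\\s", body)
    dat <- body[isMatch]
    if (!length(dat)) stop("no match-emission rows found in '", path, "'")
    rows <- lapply(dat, function(l) {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      em <- tok[3:(length(tok) - 1L)]   # drop residue, position, trailing index
      if (length(em) != 20)
        stop("HHM match row without exactly 20 emission columns in '",
             path, "'")
      v <- ifelse(em == "*", Inf, suppressWarnings(as.numeric(em)))
      if (anyNA(v)) stop("unparseable HHM emission code in '", path, "'")
      2^(-v / 1000)
    })
    m <- do.call(rbind, rows)
  }
  colnames(m) <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  new("ProfileFeatures", matrix = m, kind = kind)
}

#' Read a dataset manifest
#'
#' CSV with header \code{complex_id,protein_path,pocket_path,ligand_path,
#' affinity}; relative paths are resolved against the manifest directory.
#'
#' @param path manifest CSV path.
#' @param resolvePaths resolve relative paths against the manifest directory.
#' @return data.frame with one row per complex.
#' @export
readManifest <- function(path, resolvePaths = TRUE) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("complex_id", "protein_path", "pocket_path", "ligand_path",
            "affinity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  aff <- suppressWarnings(as.numeric(df$affinity))
  bad <- which(is.na(aff) | !is.finite(aff))
  if (length(bad))
    stop("non-numeric affinity '", df$affinity[bad[1]], "' on manifest row ",
         bad[1])
  df$affinity <- aff
  if (resolvePaths && nrow(df)) {
    base <- dirname(normalizePath(path))
    fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                              file.path(base, p))
    for (col in c("protein_path", "pocket_path", "ligand_path"))
      df[[col]] <- fix(df[[col]])
  }
  df
}

#' Write and read prediction tables
#'
#' CSV with header \code{complex_id,y_true,y_pred}; values are written with
#' enough digits to round-trip to at least 1e-6.
#'
#' @param predictions data.frame with columns complex_id, y_true, y_pred.
#' @param path output CSV path.
#' @export
writePredictions <- function(predictions, path) {
  need <- c("complex_id", "y_true", "y_pred")
  if (!all(need %in% names(predictions)))
    stop("predictions must have columns ", paste(need, collapse = ", "))
  if (nrow(predictions) &&
      !all(is.finite(predictions$y_true) & is.finite(predictions$y_pred)))
    stop("predictions must be finite")
  out <- data.frame(complex_id = predictions$complex_id,
                    y_true = sprintf("%.8f", predictions$y_true),
                    y_pred = sprintf("%.8f", predictions$y_pred))
  if (!nrow(predictions))
    out <- out[0, , drop = FALSE]
  tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write predictions to '", path,
                                    "': ", conditionMessage(e)))
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) stop("cannot read predictions: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "y_true", "y_pred")
  if (!all(need %in% names(df)))
    stop("prediction table must have columns ", paste(need, collapse = ", "))
  df$y_true <- as.numeric(df$y_true)
  df$y_pred <- as.numeric(df$y_pred)
  df
}

#' Scan a PDBbind-style directory layout into a manifest data.frame
#'
#' Convenience scanner for directories with one subdirectory per complex
#' containing \code{<id>_protein.pdb}, \code{<id>_pocket.pdb} and
#' \code{<id>_ligand.sdf} (or .mol2). Affinities must be supplied
#' separately as a named vector (pKd by complex id).
#'
#' @param dir root directory.
#' @param affinities named numeric vector of pKd values by complex id.
#' @return manifest data.frame (same schema as \code{\link{readManifest}}).
#' @export
scanComplexDirectory <- function(dir, affinities) {
  ids <- list.dirs(dir, full.names = FALSE, recursive = FALSE)
  ids <- ids[ids %in% names(affinities)]
  if (!length(ids)) stop("no complex subdirectories matching affinities in ",
                         dir)
  rows <- lapply(ids, function(id) {
    d <- file.path(dir, id)
    lig <- c(file.path(d, paste0(id, "_ligand.sdf")),
             file.path(d, paste0(id, "_ligand.mol2")))
    lig <- lig[file.exists(lig)][1]
    if (is.na(lig)) return(NULL)
    data.frame(complex_id = id,
               protein_path = file.path(d, paste0(id, "_protein.pdb")),
               pocket_path = file.path(d, paste0(id, "_pocket.pdb")),
               ligand_path = lig,
               affinity = unname(affinities[id]))
  })
  do.call(rbind, rows)
}
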