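# Sequence encoders: label, one-hot, physico-chemical and fixed-length
# padding. Unknown symbols always encode as code 0 / zero rows so that the
# feature dimension stays equal to the vocabulary size.

#' Default vocabularies
#'
#' The residue vocabulary is the 20 standard amino acids in alphabetical
#' one-letter order; the atom vocabulary lists the 27 element symbols used
#' for drug atoms (26 elements plus a catch-all \code{UNK}).
#'
#' @return character vector of symbols.
#' @export
defaultResidueVocab <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname defaultResidueVocab
#' @export
defaultAtomVocab <- function() {
  c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se", "As",
    "H", "Li", "Na", "K", "Mg", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
    "Sr", "UNK")
}

.checkVocab <- function(vocab) {
  if (anyDuplicated(vocab)) stop("vocabulary contains duplicate symbols")
  vocab
}

.asSymbols <- function(sequence) {
  if (is.character(sequence) && length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(sequence, "")[[1]] else as.character(sequence)
}

#' Label-encode a symbol sequence
#'
#' Each symbol becomes its 1-based index in the vocabulary; unknown symbols
#' become 0.
#'
#' @param sequence character vector of symbols, or a single string that is
#'   split into characters.
#' @param vocab vocabulary (ordered character vector).
#' @return integer vector of codes.
#' @export
labelEncode <- function(sequence, vocab = defaultResidueVocab()) {
  .checkVocab(vocab)
  s <- .asSymbols(sequence)
  if (!length(s)) return(integer())
  code <- match(s, vocab)
  code[is.na(code)] <- 0L
  as.integer(code)
}

#' One-hot encode a symbol sequence
#'
#' Known symbols give a single 1 in their vocabulary column; unknown symbols
#' give an all-zero row (the feature dimension stays |vocab|).
#'
#' @inheritParams labelEncode
#' @return L x |vocab| numeric matrix.
#' @export
oneHotEncode <- function(sequence, vocab = defaultResidueVocab()) {
  .checkVocab(vocab)
  s <- .asSymbols(sequence)
  m <- matrix(0, nrow = length(s), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  code <- match(s, vocab)
  known <- which(!is.na(code))
  if (length(known)) m[cbind(known, code[known])] <- 1
  m
}

#' Load a physico-chemical property table
#'
#' Reads a CSV whose first column is the symbol and remaining columns are
#' numeric properties (comment lines starting with \code{#} record the
#' provenance of each column). The shipped defaults are
#' \code{residue_properties.csv} (24 published amino-acid scales) and
#' \code{atom_properties.csv} (9 standard periodic-table properties).
#'
#' @param path CSV path; defaults to the shipped residue table.
#' @return numeric matrix with symbols as row names.
#' @export
loadPropertyTable <- function(path = system.file("extdata",
                                                 "residue_properties.csv",
                                                 package = "StructDTA")) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("property table columns must be numeric")
  rownames(m) <- df[[1]]
  m
}

#' @rdname loadPropertyTable
#' @export
residuePropertyTable <- function() loadPropertyTable()

#' @rdname loadPropertyTable
#' @export
atomPropertyTable <- function() {
  loadPropertyTable(system.file("extdata", "atom_properties.csv",
                                package = "StructDTA"))
}

#' Encode a sequence with physico-chemical properties
#'
#' Row i is the property vector of symbol i, after standardizing every
#' column to zero mean / unit variance across the table rows (deterministic;
#' computed from the table itself, never from the data). Unknown symbols give
#' zero rows; zero-variance columns standardize to zero.
#'
#' @inheritParams labelEncode
#' @param table property matrix (symbols as row names), e.g.
#'   \code{\link{residuePropertyTable}()}.
#' @return L x ncol(table) numeric matrix.
#' @export
physchemEncode <- function(sequence, table = residuePropertyTable()) {
  if (is.null(rownames(table))) stop("property table needs symbol row names")
  mu <- colMeans(table)
  sdv <- apply(table, 2, sd)
  sdv[sdv == 0] <- Inf   # constant column -> zeros
  std <- sweep(sweep(table, 2, mu, "-"), 2, sdv, "/")
  s <- .asSymbols(sequence)
  out <- matrix(0, nrow = length(s), ncol = ncol(table),
                dimnames = list(NULL, colnames(table)))
  idx <- match(s, rownames(table))
  known <- which(!is.na(idx))
  if (length(known)) out[known, ] <- std[idx[known], , drop = FALSE]
  out
}

#' Pad or truncate a feature matrix to a fixed length
#'
#' Shorter inputs get all-zero rows appended; longer inputs are cut at
#' \code{fixedLength} with the truncation recorded. The first
#' \code{trueLength} rows are carried over bit-exactly.
#'
#' @param matrix L x d numeric matrix.
#' @param fixedLength target row count (targets default to 2100, pockets to
#'   125 in the model configuration).
#' @return an \linkS4class{EncodedSequence}.
#' @export
padOrTruncate <- function(matrix, fixedLength) {
  if (fixedLength < 1) stop("fixedLength must be >= 1")
  L <- nrow(matrix)
  tl <- min(L, fixedLength)
  truncated <- L > fixedLength
  out <- matrix(0, nrow = fixedLength, ncol = ncol(matrix))
  if (!is.null(colnames(matrix))) colnames(out) <- colnames(matrix)
  if (tl) out[seq_len(tl), ] <- matrix[seq_len(tl), , drop = FALSE]
  new("EncodedSequence", matrix = out, trueLength = as.integer(tl),
      mask = seq_len(fixedLength) <= tl, truncated = truncated)
}
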