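#' @import methods
#' @importFrom stats cor rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# Standard three-letter -> one-letter residue map. Anything outside these 20
# codes (MSE, PTR, ...) is reported as 'X'; the encoders then treat it as an
# unknown symbol (zero feature row).
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.AA1TO3 <- setNames(names(.AA3TO1), unname(.AA3TO1))

.ELEMENT_SYMBOLS <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U")

#' Protein structure reduced to its C-alpha trace
#'
#' One row of \code{residues} per residue that carries a C-alpha atom, in
#' file order: \code{chain}, \code{resno}, \code{insert}, \code{resid}
#' (three-letter code), \code{code} (one-letter code, \code{"X"} for
#' nonstandard residues) and the C-alpha coordinates \code{x}, \code{y},
#' \code{z} in Angstrom. \code{nSkipped} counts residues that appeared in the
#' file without a C-alpha record.
#'
#' @slot id character identifier.
#' @slot residues data.frame as described above.
#' @slot chains character vector of chain identifiers in file order.
#' @slot nSkipped integer count of residues dropped for lack of a C-alpha.
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  slots = c(id = "character", residues = "data.frame",
            chains = "character", nSkipped = "integer"))

setValidity("ProteinStructure", function(object) {
  r <- object@residues
  need <- c("chain", "resno", "insert", "resid", "code", "x", "y", "z")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns", paste(need, collapse = ", ")))
  if (nrow(r) < 1L) return("structure must contain at least one residue")
  if (!all(r$code %in% c(unname(.AA3TO1), "X")))
    return("one-letter codes must be standard amino acids or 'X'")
  if (!all(is.finite(c(r$x, r$y, r$z))))
    return("C-alpha coordinates must be finite")
  TRUE
})

#' Small-molecule ligand: atoms and covalent bonds
#'
#' @slot id character identifier.
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (Angstrom), in file order.
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, \code{i < j}) and integer \code{order}.
#' @exportClass LigandMolecule
setClass("LigandMolecule",
  slots = c(id = "character", atoms = "data.frame", bonds = "data.frame"))

setValidity("LigandMolecule", function(object) {
  a <- object@atoms; b <- object@bonds
  if (!all(c("element", "x", "y", "z") %in% names(a)))
    return("atoms must have columns element, x, y, z")
  if (!all(c("i", "j", "order") %in% names(b)))
    return("bonds must have columns i, j, order")
  if (!all(a$element %in% .ELEMENT_SYMBOLS))
    return(paste("invalid element symbol:",
                 paste(setdiff(a$element, .ELEMENT_SYMBOLS), collapse = ",")))
  if (nrow(b)) {
    if (any(b$i == b$j)) return("self-bond (i == j) not allowed")
    if (any(b$i < 1 | b$j < 1 | b$i > nrow(a) | b$j > nrow(a)))
      return("bond endpoint outside atom range")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) return("duplicate undirected bond")
  }
  TRUE
})

#' Per-residue sequence profile (PSSM or HMM emissions)
#'
#' @slot matrix L x 20 numeric matrix; PSSM scores are kept as given,
#'   HMM match-emission codes are converted to probabilities.
#' @slot kind either \code{"PSSM"} or \code{"HMM"}.
#' @exportClass ProfileFeatures
setClass("ProfileFeatures", slots = c(matrix = "matrix", kind = "character"))

setValidity("ProfileFeatures", function(object) {
  if (ncol(object@matrix) != 20L) return("profile must have exactly 20 columns")
  if (!object@kind %in% c("PSSM", "HMM")) return("kind must be PSSM or HMM")
  TRUE
})

#' Fixed-length encoded sequence
#'
#' @slot matrix fixed_length x d numeric matrix, zero rows beyond
#'   \code{trueLength}.
#' @slot trueLength number of real (non-padding) rows.
#' @slot mask logical vector, TRUE exactly for the first \code{trueLength}
#'   rows.
#' @slot truncated TRUE when the input was longer than the fixed length.
#' @exportClass EncodedSequence
setClass("EncodedSequence",
  slots = c(matrix = "matrix", trueLength = "integer",
            mask = "logical", truncated = "logical"))

setValidity("EncodedSequence", function(object) {
  L <- nrow(object@matrix)
  tl <- object@trueLength
  if (length(object@mask) != L) return("mask length must equal matrix rows")
  if (tl < 0L || tl > L) return("trueLength out of range")
  if (!identical(object@mask, seq_len(L) <= tl))
    return("mask must be TRUE exactly for the first trueLength rows")
  if (tl < L && any(object@matrix[(tl + 1L):L, ] != 0))
    return("padding rows must be all-zero")
  TRUE
})

#' Undirected vertex-featured graph
#'
#' Shared representation for residue contact graphs and molecular graphs.
#' Edges are stored once with \code{i < j}; no self-edges.
#'
#' @slot nVertices vertex count.
#' @slot edges m x 2 integer matrix of undirected edges (\code{i < j}).
#' @slot features nVertices x d numeric vertex-feature matrix.
#' @slot labels optional character vertex labels (residue/atom identifiers).
#' @exportClass SimpleGraph
setClass("SimpleGraph",
  slots = c(nVertices = "integer", edges = "matrix",
            features = "matrix", labels = "character"))

setValidity("SimpleGraph", function(object) {
  n <- object@nVertices
  e <- object@edges
  if (n < 1L) return("graph must have at least one vertex")
  if (ncol(e) != 2L) return("edges must be a 2-column matrix")
  if (nrow(e)) {
    if (any(e[, 1] >= e[, 2])) return("edges must be stored with i < j")
    if (any(e < 1L | e > n)) return("edge index out of range")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) return("duplicate edge")
  }
  if (nrow(object@features) != n)
    return("feature rows must equal vertex count")
  if (length(object@labels) && length(object@labels) != n)
    return("labels length must equal vertex count")
  TRUE
})

#' Disjoint union of several graphs
#'
#' @slot graph the block-diagonal union as a \linkS4class{SimpleGraph}.
#' @slot membership integer vector mapping each vertex to its source graph.
#' @slot sizes vertex count per source graph.
#' @exportClass BatchedGraph
setClass("BatchedGraph",
  slots = c(graph = "SimpleGraph", membership = "integer", sizes = "integer"))

setValidity("BatchedGraph", function(object) {
  if (sum(object@sizes) != object@graph@nVertices)
    return("sizes must sum to the union vertex count")
  if (length(object@membership) != object@graph@nVertices)
    return("membership length must equal vertex count")
  e <- object@graph@edges
  if (nrow(e) && any(object@membership[e[, 1]] != object@membership[e[, 2]]))
    return("edges must not cross graph boundaries")
  TRUE
})

#' One featurized drug-target-pocket complex
#'
#' Unit of training and evaluation: the parsed protein, the pocket as an
#' index subset of the protein residues, the three graphs and the affinity
#' label. \code{cache} holds precomputed encoder inputs (one-hot sequence
#' matrices and unrolled convolution inputs) keyed by the model config used
#' at featurization time.
#'
#' @slot id complex identifier.
#' @slot affinity experimental pKd (-log10 Kd).
#' @slot protein \linkS4class{ProteinStructure} of the full target.
#' @slot pocketIndex integer indices of pocket residues within the target.
#' @slot drug \linkS4class{SimpleGraph} molecular graph (heavy atoms).
#' @slot targetGraph \linkS4class{SimpleGraph} residue contact graph.
#' @slot pocketGraph \linkS4class{SimpleGraph} contact graph over pocket
#'   residues only.
#' @slot cache list of precomputed encoder inputs.
#' @exportClass ComplexSample
setClass("ComplexSample",
  slots = c(id = "character", affinity = "numeric",
            protein = "ProteinStructure", pocketIndex = "integer",
            drug = "SimpleGraph", targetGraph = "SimpleGraph",
            pocketGraph = "SimpleGraph", cache = "list"))

setValidity("ComplexSample", function(object) {
  if (!is.finite(object@affinity)) return("affinity must be finite")
  n <- nrow(object@protein@residues)
  if (length(object@pocketIndex) < 1L) return("pocket must be nonempty")
  if (any(object@pocketIndex < 1L | object@pocketIndex > n))
    return("pocket index out of range")
  TRUE
})

#' Bidirectional attention score matrices
#'
#' Row-stochastic interaction scores in both directions between drug heavy
#' atoms and target residues.
#'
#' @slot atomsToResidues n_atoms x n_residues matrix, each row sums to 1.
#' @slot residuesToAtoms n_residues x n_atoms matrix, each row sums to 1.
#' @exportClass AttentionResult
setClass("AttentionResult",
  slots = c(atomsToResidues = "matrix", residuesToAtoms = "matrix"))

setValidity("AttentionResult", function(object) {
  a <- object@atomsToResidues; r <- object@residuesToAtoms
  if (nrow(a) != ncol(r) || ncol(a) != nrow(r))
    return("matrices must be mutual transposed shapes")
  if (any(a <= 0) || any(a > 1) || any(r <= 0) || any(r > 1))
    return("attention entries must lie in (0, 1]")
  if (max(abs(rowSums(a) - 1)) > 1e-6 || max(abs(rowSums(r) - 1)) > 1e-6)
    return("attention rows must sum to 1 within 1e-6")
  TRUE
})

#' Regression evaluation report
#'
#' The six affinity-regression metrics: mean absolute error, root mean
#' square error, Pearson and Spearman correlation, concordance index and
#' coefficient of determination.
#'
#' @slot mae,rmse,pcc,spearman,ci,r2 numeric scalars.
#' @slot n number of evaluated pairs.
#' @exportClass MetricsReport
setClass("MetricsReport",
  slots = c(mae = "numeric", rmse = "numeric", pcc = "numeric",
            spearman = "numeric", ci = "numeric", r2 = "numeric",
            n = "integer"))
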