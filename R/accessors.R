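# Generics and accessors; slot access stays internal to the package.

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("proteinSequence", function(x) standardGeneric("proteinSequence"))

#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("skipCount", function(x) standardGeneric("skipCount"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))

#' @rdname accessors
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))

#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname accessors
#' @export
setGeneric("vertexFeatures", function(x) standardGeneric("vertexFeatures"))

#' @rdname accessors
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname accessors
#' @export
setGeneric("graphMembership", function(x) standardGeneric("graphMembership"))

#' @rdname accessors
#' @export
setGeneric("affinity", function(x) standardGeneric("affinity"))

#' @rdname accessors
#' @export
setGeneric("pocketMask", function(x) standardGeneric("pocketMask"))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname accessors
#' @export
setGeneric("encodedMatrix", function(x) standardGeneric("encodedMatrix"))

#' @rdname accessors
#' @export
setGeneric("trueLength", function(x) standardGeneric("trueLength"))

#' @rdname accessors
#' @export
setGeneric("wasTruncated", function(x) standardGeneric("wasTruncated"))

#' @rdname accessors
#' @export
setGeneric("atomsToResidues", function(x) standardGeneric("atomsToResidues"))

#' @rdname accessors
#' @export
setGeneric("residuesToAtoms", function(x) standardGeneric("residuesToAtoms"))

#' Accessors for StructDTA objects
#'
#' Read-only views of the S4 containers: residue sequences and coordinates,
#' ligand atoms and bonds, graph structure, encoded matrices, attention
#' matrices and metric values.
#'
#' @name accessors
#' @aliases proteinSequence caCoords nResidues skipCount nAtoms elements
#'   bondTable nVertices edgeMatrix vertexFeatures vertexLabels
#'   graphMembership affinity pocketMask profileMatrix encodedMatrix
#'   trueLength wasTruncated atomsToResidues residuesToAtoms
NULL

#' @rdname accessors
#' @export
setMethod("proteinSequence", "ProteinStructure",
          function(x) paste(x@residues$code, collapse = ""))

#' @rdname accessors
#' @export
setMethod("caCoords", "ProteinStructure",
          function(x) as.matrix(x@residues[, c("x", "y", "z")]))

#' @rdname accessors
#' @export
setMethod("nResidues", "ProteinStructure", function(x) nrow(x@residues))

#' @rdname accessors
#' @export
setMethod("skipCount", "ProteinStructure", function(x) x@nSkipped)

#' @rdname accessors
#' @export
setMethod("nAtoms", "LigandMolecule", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setMethod("elements", "LigandMolecule", function(x) x@atoms$element)

#' @rdname accessors
#' @export
setMethod("bondTable", "LigandMolecule", function(x) x@bonds)

#' @rdname accessors
#' @export
setMethod("nVertices", "SimpleGraph", function(x) x@nVertices)

#' @rdname accessors
#' @export
setMethod("edgeMatrix", "SimpleGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("vertexFeatures", "SimpleGraph", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("vertexLabels", "SimpleGraph", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("nVertices", "BatchedGraph", function(x) x@graph@nVertices)

#' @rdname accessors
#' @export
setMethod("edgeMatrix", "BatchedGraph", function(x) x@graph@edges)

#' @rdname accessors
#' @export
setMethod("graphMembership", "BatchedGraph", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("affinity", "ComplexSample", function(x) x@affinity)

#' @rdname accessors
#' @export
setMethod("pocketMask", "ComplexSample", function(x) {
  m <- rep(FALSE, nrow(x@protein@residues))
  m[x@pocketIndex] <- TRUE
  m
})

#' @rdname accessors
#' @export
setMethod("profileMatrix", "ProfileFeatures", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("encodedMatrix", "EncodedSequence", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("trueLength", "EncodedSequence", function(x) x@trueLength)

#' @rdname accessors
#' @export
setMethod("wasTruncated", "EncodedSequence", function(x) x@truncated)

#' @rdname accessors
#' @export
setMethod("atomsToResidues", "AttentionResult", function(x) x@atomsToResidues)

#' @rdname accessors
#' @export
setMethod("residuesToAtoms", "AttentionResult", function(x) x@residuesToAtoms)

#' Convert a metrics report to a named list
#'
#' @param report a \linkS4class{MetricsReport}.
#' @return named list with elements mae, rmse, pcc, spearman, ci, r2, n.
#' @export
metricsAsList <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  list(mae = report@mae, rmse = report@rmse, pcc = report@pcc,
       spearman = report@spearman, ci = report@ci, r2 = report@r2,
       n = report@n)
}

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure '%s': %d residues, %d chain(s), %d skipped\n",
              object@id, nrow(object@residues), length(object@chains),
              object@nSkipped))
  s <- proteinSequence(object)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" sequence:", s, "\n")
})

setMethod("show", "LigandMolecule", function(object) {
  cat(sprintf("LigandMolecule '%s': %d atoms (%s), %d bonds\n", object@id,
              nrow(object@atoms),
              paste(names(sort(-table(object@atoms$element))), collapse = ","),
              nrow(object@bonds)))
})

setMethod("show", "SimpleGraph", function(object) {
  cat(sprintf("SimpleGraph: %d vertices, %d edges, %d-dim features\n",
              object@nVertices, nrow(object@edges), ncol(object@features)))
})

setMethod("show", "BatchedGraph", function(object) {
  cat(sprintf("BatchedGraph: %d graphs, %d vertices total, %d edges\n",
              length(object@sizes), object@graph@nVertices,
              nrow(object@graph@edges)))
})

setMethod("show", "ComplexSample", function(object) {
  cat(sprintf(
    "ComplexSample '%s': %d residues (pocket %d), %d heavy atoms, pKd %.3f\n",
    object@id, nrow(object@protein@residues), length(object@pocketIndex),
    object@drug@nVertices, object@affinity))
})

setMethod("show", "AttentionResult", function(object) {
  cat(sprintf("AttentionResult: %d atoms x %d residues (row-stochastic both ways)\n",
              nrow(object@atomsToResidues), ncol(object@atomsToResidues)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (n=%d): MAE %.4f  RMSE %.4f  PCC %.4f  Spearman %.4f  CI %.4f  R2 %.4f\n",
    object@n, object@mae, object@rmse, object@pcc, object@spearman,
    object@ci, object@r2))
})
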