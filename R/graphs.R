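# Residue contact graphs, molecular graphs, batching and a plain-text
# graph archive for caching featurized datasets.

.normalizeEdges <- function(edges) {
  edges <- as.matrix(edges)
  if (!nrow(edges))
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  e <- cbind(i = as.integer(pmin(edges[, 1], edges[, 2])),
             j = as.integer(pmax(edges[, 1], edges[, 2])))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
  e[order(e[, 1], e[, 2]), , drop = FALSE]   # canonical (i, j) order
}

#' Build a residue contact graph from a C-alpha trace
#'
#' Vertices are the residues in sequence order; an undirected edge joins
#' residues i and j (i != j) whenever their C-alpha Euclidean distance is
#' at most \code{cutoff} Angstrom (closed boundary, double precision).
#' Vertex features are supplied by the caller (e.g. one-hot rows or sliced
#' sequence-encoder output); extra padded feature rows beyond the residue
#' count are sliced off, fewer rows than residues is an error.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param features numeric matrix with at least nResidues rows.
#' @param cutoff contact distance cutoff in Angstrom (default 8).
#' @return a \linkS4class{SimpleGraph}.
#' @export
buildResidueGraph <- function(structure, features, cutoff = 8.0) {
  n <- nResidues(structure)
  features <- as.matrix(features)
  if (nrow(features) < n)
    stop("feature matrix has ", nrow(features), " rows for ", n, " residues")
  features <- features[seq_len(n), , drop = FALSE]
  xyz <- caCoords(structure)
  d <- as.matrix(dist(xyz))
  adj <- d <= cutoff
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  e <- which(adj, arr.ind = TRUE)
  edges <- .normalizeEdges(cbind(e[, 1], e[, 2]))
  r <- structure@residues
  new("SimpleGraph", nVertices = as.integer(n), edges = edges,
      features = features,
      labels = paste0(r$chain, r$resno, r$insert, ":", r$code))
}

#' Build a molecular graph from a ligand
#'
#' Atoms are vertices (hydrogens and their bonds removed unless
#' \code{includeHydrogens}); vertex features are the one-hot encoding of the
#' element over the atom vocabulary; edges are the remaining covalent bonds,
#' undirected and deduplicated. Bonds to removed atoms are removed with
#' them, never left dangling.
#'
#' @param mol a \linkS4class{LigandMolecule}.
#' @param vocab atom vocabulary (default \code{\link{defaultAtomVocab}()},
#'   27 symbols).
#' @param includeHydrogens keep hydrogen atoms (default FALSE).
#' @return a \linkS4class{SimpleGraph}.
#' @export
buildMolecularGraph <- function(mol, vocab = defaultAtomVocab(),
                                includeHydrogens = FALSE) {
  el <- elements(mol)
  keep <- if (includeHydrogens) seq_along(el) else which(el != "H")
  if (!length(keep)) stop("no atoms left after hydrogen removal")
  remap <- rep(NA_integer_, length(el))
  remap[keep] <- seq_along(keep)
  b <- bondTable(mol)
  if (nrow(b)) {
    ok <- !is.na(remap[b$i]) & !is.na(remap[b$j])
    edges <- .normalizeEdges(cbind(remap[b$i[ok]], remap[b$j[ok]]))
  } else {
    edges <- .normalizeEdges(matrix(integer(), ncol = 2))
  }
  elKeep <- el[keep]
  new("SimpleGraph", nVertices = length(keep), edges = edges,
      features = oneHotEncode(elKeep, vocab),
      labels = paste0(elKeep, keep))
}

#' Batch graphs into a disjoint union
#'
#' Block-diagonal union with an index offset per graph; no edges cross
#' graph boundaries. \code{unbatchGraphs} recovers the originals exactly.
#'
#' @param graphs list of \linkS4class{SimpleGraph} sharing one feature
#'   dimension.
#' @return a \linkS4class{BatchedGraph}.
#' @export
batchGraphs <- function(graphs) {
  if (!length(graphs)) stop("cannot batch an empty graph list")
  d <- vapply(graphs, function(g) ncol(g@features), integer(1))
  if (length(unique(d)) != 1L)
    stop("graphs have mixed feature dimensions: ",
         paste(unique(d), collapse = ", "))
  sizes <- vapply(graphs, nVertices, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]@edges
    if (nrow(e)) e + offsets[k] else e
  }))
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2)
  labels <- unlist(lapply(graphs, function(g)
    if (length(g@labels)) g@labels else rep("", nVertices(g))))
  union <- new("SimpleGraph", nVertices = sum(sizes),
               edges = .normalizeEdges(edges),
               features = do.call(rbind, lapply(graphs, vertexFeatures)),
               labels = labels)
  new("BatchedGraph", graph = union,
      membership = rep(seq_along(graphs), sizes), sizes = sizes)
}

#' @rdname batchGraphs
#' @param batched a \linkS4class{BatchedGraph}.
#' @export
unbatchGraphs <- function(batched) {
  sizes <- batched@sizes
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  g <- batched@graph
  lapply(seq_along(sizes), function(k) {
    idx <- offsets[k] + seq_len(sizes[k])
    inK <- batched@membership[g@edges[, 1]] == k
    e <- g@edges[inK, , drop = FALSE]
    if (nrow(e)) e <- e - offsets[k]
    new("SimpleGraph", nVertices = sizes[k],
        edges = .normalizeEdges(e),
        features = g@features[idx, , drop = FALSE],
        labels = if (length(g@labels)) g@labels[idx] else character())
  })
}

#' Serialize a graph to / from a plain-text archive
#'
#' JSON with vertex count, edge list, feature matrix and labels; used to
#' cache featurized datasets.
#'
#' @param graph a \linkS4class{SimpleGraph}.
#' @param path output path.
#' @export
writeGraphArchive <- function(graph, path) {
  obj <- list(n_vertices = graph@nVertices,
              edges = unname(graph@edges),
              features = unname(graph@features),
              labels = graph@labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGraphArchive
#' @export
readGraphArchive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges)) matrix(as.integer(obj$edges), ncol = 2)
           else matrix(integer(), ncol = 2)
  feat <- matrix(as.numeric(obj$features), nrow = obj$n_vertices)
  new("SimpleGraph", nVertices = as.integer(obj$n_vertices),
      edges = .normalizeEdges(edges), features = feat,
      labels = as.character(obj$labels %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
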