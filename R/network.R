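#' Construct a NetworkSpec
#'
#' Builds the canonical representation of an undirected network topology.
#' Edges may be given as vertex names or as integer indices; they are
#' normalized to index pairs \code{(i, j)} with \code{i < j}, self-loops
#' are dropped, duplicates (in either orientation) are collapsed, and the
#' result is sorted lexicographically so that the canonical edge index
#' k <-> (i, j) — and hence positions M+1..M+K of the score vector — is
#' deterministic.
#'
#' @param vertexNames character vector of M unique vertex identifiers.
#' @param edges a K x 2 matrix (or data frame) of edges, either character
#'   (vertex names) or numeric (1-based vertex indices).
#' @param quiet suppress the message reporting dropped self-loops and
#'   duplicate edges.
#'
#' @return a [NetworkSpec-class] object.
#' @examples
#' net <- NetworkSpec(c("A", "B", "C"),
#'                    rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' edgeNames(net)
#' @export
NetworkSpec <- function(vertexNames, edges, quiet = FALSE) {
  vertexNames <- as.character(vertexNames)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    e <- matrix(integer(0), ncol = 2L)
  } else {
    if (is.character(edges)) {
      idx <- match(edges, vertexNames)
      if (anyNA(idx)) {
        bad <- unique(edges[is.na(idx)])
        stop("edge list refers to unknown vertices: ",
             paste(bad, collapse = ", "))
      }
      e <- matrix(as.integer(idx), ncol = 2L)
    } else {
      e <- matrix(as.integer(edges), ncol = 2L)
      if (any(e < 1L | e > length(vertexNames), na.rm = TRUE) || anyNA(e))
        stop("edge indices must lie in 1..M")
    }
    selfLoops <- e[, 1L] == e[, 2L]
    e <- e[!selfLoops, , drop = FALSE]
    flip <- e[, 1L] > e[, 2L]
    e[flip, ] <- e[flip, c(2L, 1L)]
    dup <- duplicated(paste(e[, 1L], e[, 2L]))
    nDropped <- sum(selfLoops) + sum(dup)
    e <- e[!dup, , drop = FALSE]
    if (nDropped > 0L && !quiet)
      message("dropped ", sum(selfLoops), " self-loop(s) and ",
              sum(dup), " duplicate edge(s)")
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  dimnames(e) <- NULL
  new("NetworkSpec", vertexNames = vertexNames, edges = e)
}

#' Accessors for NetworkSpec
#'
#' @param object a [NetworkSpec-class].
#' @param vertex a vertex name or 1-based index.
#' @return \code{vertexNames}: character vector; \code{vertexCount},
#'   \code{edgeCount}, \code{vertexDegree}: integer; \code{edgeMatrix}:
#'   K x 2 integer matrix; \code{edgeNames}: character vector like
#'   \code{"A--B"} in canonical edge order.
#' @name NetworkSpec-accessors
#' @aliases vertexNames vertexCount edgeCount edgeMatrix edgeNames vertexDegree
NULL

#' @rdname NetworkSpec-accessors
#' @export
setMethod("vertexNames", "NetworkSpec", function(object) object@vertexNames)

#' @rdname NetworkSpec-accessors
#' @export
setMethod("vertexCount", "NetworkSpec",
          function(object) length(object@vertexNames))

#' @rdname NetworkSpec-accessors
#' @export
setMethod("edgeCount", "NetworkSpec", function(object) nrow(object@edges))

#' @rdname NetworkSpec-accessors
#' @export
setMethod("edgeMatrix", "NetworkSpec", function(object) object@edges)

#' @rdname NetworkSpec-accessors
#' @export
setMethod("edgeNames", "NetworkSpec", function(object) {
  v <- object@vertexNames
  if (nrow(object@edges) == 0L) return(character(0))
  paste0(v[object@edges[, 1L]], "--", v[object@edges[, 2L]])
})

#' @rdname NetworkSpec-accessors
#' @export
setMethod("vertexDegree", "NetworkSpec", function(object, vertex) {
  i <- .resolveVertex(object, vertex)
  sum(object@edges == i)
})

setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec with", vertexCount(object), "vertices and",
      edgeCount(object), "edges\n")
  v <- vertexNames(object)
  cat("  vertices:", paste(utils::head(v, 6), collapse = ", "),
      if (length(v) > 6) "...", "\n")
  e <- edgeNames(object)
  if (length(e))
    cat("  edges:   ", paste(utils::head(e, 6), collapse = ", "),
        if (length(e) > 6) "...", "\n")
})

.resolveVertex <- function(net, vertex) {
  if (is.character(vertex)) {
    i <- match(vertex, net@vertexNames)
    if (is.na(i)) stop("unknown vertex: ", vertex)
  } else {
    i <- as.integer(vertex)
    if (is.na(i) || i < 1L || i > length(net@vertexNames))
      stop("vertex index out of range: ", vertex)
  }
  i
}

#' Read a network edge list from a delimited file
#'
#' Reads a two-column (or wider; extra columns ignored) delimited file of
#' vertex-name pairs and returns the canonical [NetworkSpec-class].
#' Vertices are taken in order of first appearance unless a vertex
#' universe is supplied (e.g. the column names of the paired data matrix),
#' in which case every edge endpoint must belong to it — this prevents
#' silent misalignment between matrix columns and network vertices.
#'
#' @param path path to the edge-list file.
#' @param delimiter field delimiter (default tab).
#' @param header logical; does the file carry a header row?
#' @param vertexUniverse optional character vector fixing the vertex set
#'   and order.
#' @return a [NetworkSpec-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tC", "A\tC"), f)
#' loadEdgeList(f)
#' @export
loadEdgeList <- function(path, delimiter = "\t", header = FALSE,
                         vertexUniverse = NULL) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  tab <- utils::read.table(path, sep = delimiter, header = header,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", fill = FALSE,
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2L)
    stop("edge list must have at least two columns (vertex-name pairs)")
  pairs <- as.matrix(tab[, 1:2])
  if (any(pairs == ""))
    stop("edge list contains a row with fewer than two fields")
  if (is.null(vertexUniverse)) {
    verts <- unique(as.vector(t(pairs)))
  } else {
    verts <- as.character(vertexUniverse)
    missing <- setdiff(unique(as.vector(pairs)), verts)
    if (length(missing))
      stop("edge-list vertices absent from the vertex universe: ",
           paste(missing, collapse = ", "))
  }
  net <- NetworkSpec(verts, pairs)
  if (edgeCount(net) == 0L)
    stop("empty edge set after normalization; a network test needs K >= 1")
  net
}

#' Write a network edge list to a delimited file
#'
#' Inverse of [loadEdgeList()]: writes one edge per row, endpoints as
#' vertex names in canonical order, so that load -> write -> load
#' round-trips to an identical topology.
#'
#' @param net a [NetworkSpec-class].
#' @param path output path.
#' @param delimiter field delimiter (default tab).
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(net, path, delimiter = "\t") {
  v <- vertexNames(net)
  e <- edgeMatrix(net)
  lines <- paste(v[e[, 1L]], v[e[, 2L]], sep = delimiter)
  writeLines(lines, path)
  invisible(path)
}

#' Star subnetwork of a focal vertex
#'
#' Returns the subnetwork consisting of a focal vertex, its neighbors and
#' exactly the edges incident to the focal vertex.  Treating a vertex
#' together with its connected edges as a network of its own is how the
#' whole-network test is localized to individual vertices (see
#' [vertexSubnetworkTest()]).
#'
#' @param net a [NetworkSpec-class].
#' @param vertex vertex name or index.
#' @return a [NetworkSpec-class]; an isolated vertex yields K = 0, which
#'   downstream tests flag as untestable.
#' @export
incidentSubnetwork <- function(net, vertex) {
  i <- .resolveVertex(net, vertex)
  e <- edgeMatrix(net)
  hit <- e[, 1L] == i | e[, 2L] == i
  inc <- e[hit, , drop = FALSE]
  keep <- sort(unique(c(i, as.vector(inc))))
  v <- vertexNames(net)[keep]
  remap <- match(as.vector(inc), keep)
  NetworkSpec(v, matrix(remap, ncol = 2L), quiet = TRUE)
}

#' Drop weakly correlated edges
#'
#' Shrinkage remedy for a (near-)singular score covariance: removes every
#' edge whose pooled (both groups combined, label-blind) Pearson
#' correlation is smaller in magnitude than a threshold, leaving the
#' vertex set unchanged.  Pruning first and then testing the remaining
#' network restores invertibility of the score covariance in dense or
#' weakly-connected networks.
#'
#' @param net a [NetworkSpec-class].
#' @param data a [LabeledDataset-class] whose columns cover the network's
#'   vertices.
#' @param threshold correlation magnitude in [0, 1); edges with
#'   \code{|r| < threshold} are removed.
#' @return a [NetworkSpec-class] with the surviving edges.
#' @export
pruneEdges <- function(net, data, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop("threshold must lie in [0, 1)")
  X <- .alignColumns(data, net)
  e <- edgeMatrix(net)
  if (nrow(e) == 0L) return(net)
  r <- vapply(seq_len(nrow(e)), function(k)
    stats::cor(X[, e[k, 1L]], X[, e[k, 2L]]), numeric(1))
  keep <- abs(r) >= threshold
  NetworkSpec(vertexNames(net), e[keep, , drop = FALSE], quiet = TRUE)
}

# Align a dataset's columns to a network's vertex order; errors if any
# network vertex is missing from the data.
.alignColumns <- function(data, net) {
  X <- dataMatrix(data)
  idx <- match(vertexNames(net), colnames(X))
  if (anyNA(idx))
    stop("data columns do not cover network vertices: ",
         paste(vertexNames(net)[is.na(idx)], collapse = ", "))
  X[, idx, drop = FALSE]
}
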