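#' Read a vertex-to-feature map
#'
#' Two-column delimited file (vertex, feature) mapping each network vertex
#' to the raw feature columns (probe sets, SNPs) that measure it.
#'
#' @param path path to the file.
#' @param delimiter field delimiter (default tab).
#' @param header does the file carry a header row?
#' @return named list: vertex name -> character vector of feature names.
#' @export
loadFeatureMap <- function(path, delimiter = "\t", header = FALSE) {
  tab <- utils::read.table(path, sep = delimiter, header = header,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("feature map needs two columns (vertex, feature)")
  split(tab[[2L]], factor(tab[[1L]], levels = unique(tab[[1L]])))
}

.checkFeatureMap <- function(raw, featureMap) {
  if (!length(featureMap)) stop("empty feature map")
  for (v in names(featureMap)) {
    f <- featureMap[[v]]
    if (!length(f)) stop("vertex '", v, "' maps to an empty feature list")
    missing <- setdiff(f, colnames(raw))
    if (length(missing))
      stop("features absent from the raw matrix for vertex '", v, "': ",
           paste(missing, collapse = ", "))
  }
}

#' Collapse features to vertices by averaging
#'
#' Per-sample arithmetic mean of the mapped feature columns for each
#' vertex — the standard collapse when several probe sets measure the
#' same gene.
#'
#' @param raw numeric samples x features matrix with feature column names.
#' @param featureMap named list, vertex name -> feature names (see
#'   [loadFeatureMap()]).
#' @return samples x vertices numeric matrix.
#' @export
averageFeatures <- function(raw, featureMap) {
  .checkFeatureMap(raw, featureMap)
  out <- vapply(featureMap, function(f)
    rowMeans(raw[, f, drop = FALSE]), numeric(nrow(raw)))
  colnames(out) <- names(featureMap)
  rownames(out) <- rownames(raw)
  out
}

#' Collapse features to vertices by first principal component
#'
#' Per-vertex PC1 scores of the mapped feature block: features are
#' standardized (correlation-matrix PCA) on the pooled sample, ignoring
#' group labels so no group information leaks into vertex construction,
#' and the score vector is the leading eigenvector projection.  The sign
#' is fixed by requiring the largest-magnitude loading to be positive
#' (the score statistic is not sign-invariant in the vertex block, so a
#' deterministic orientation is required).  A single-feature vertex
#' passes through as its standardized column.
#'
#' @param raw numeric samples x features matrix (>= 2 samples).
#' @param featureMap named list, vertex name -> feature names.
#' @return samples x vertices matrix of PC1 scores.
#' @export
firstPC <- function(raw, featureMap) {
  .checkFeatureMap(raw, featureMap)
  if (nrow(raw) < 2L) stop("need >= 2 samples for principal components")
  out <- vapply(featureMap, function(f) {
    B <- raw[, f, drop = FALSE]
    sds <- apply(B, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance feature(s) in block: ",
           paste(f[sds == 0], collapse = ", "))
    Bs <- scale(B)
    v <- eigen(stats::cor(B), symmetric = TRUE)$vectors[, 1L]
    if (v[which.max(abs(v))] < 0) v <- -v
    drop(Bs %*% v)
  }, numeric(nrow(raw)))
  colnames(out) <- names(featureMap)
  rownames(out) <- rownames(raw)
  out
}

#' Collapse a raw feature matrix into a LabeledDataset
#'
#' Applies [averageFeatures()] or [firstPC()] and attaches the group
#' labels, yielding the per-vertex dataset the network tests consume.
#'
#' @param raw numeric samples x features matrix.
#' @param y binary 0/1 group labels.
#' @param featureMap named list, vertex name -> feature names.
#' @param method \code{"mean"} or \code{"pc1"}.
#' @return a [LabeledDataset-class] with one column per vertex.
#' @export
collapseFeatures <- function(raw, y, featureMap,
                             method = c("mean", "pc1")) {
  method <- match.arg(method)
  X <- switch(method,
              mean = averageFeatures(raw, featureMap),
              pc1 = firstPC(raw, featureMap))
  LabeledDataset(X, y)
}
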