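#' Fisher r-to-z transform
#'
#' \eqn{z = \tfrac12 \log((1+r)/(1-r))}, the variance-stabilizing
#' transform of a Pearson correlation.  Inputs at exactly +/-1 (possible on
#' degenerate finite samples) are clipped to +/-(1 - 1e-12) with a warning.
#'
#' @param r correlation value(s) in [-1, 1].
#' @return transformed value(s); a monotone odd function of r.
#' @examples
#' fisherZ(0.5)  # 0.5 * log(3)
#' @export
fisherZ <- function(r) {
  if (any(!is.finite(r))) stop("non-finite correlation passed to fisherZ")
  hi <- abs(r) >= 1
  if (any(hi)) {
    warning("correlation(s) at +/-1 clipped to +/-(1 - 1e-12)")
    r[hi] <- sign(r[hi]) * (1 - 1e-12)
  }
  0.5 * log((1 + r) / (1 - r))
}

# Split the rows of X by group; cases first.
.groupSplit <- function(data) {
  y <- groupLabels(data)
  X <- dataMatrix(data)
  list(D = X[y == 1L, , drop = FALSE], C = X[y == 0L, , drop = FALSE])
}

#' Standardized per-vertex mean difference
#'
#' \eqn{T_i = (\bar x_i^D - \bar x_i^C) / \sqrt{\mathrm{var}(\bar x_i^D)
#' + \mathrm{var}(\bar x_i^C)}}, where the variance of each group mean is
#' estimated as the group sample variance divided by the group size
#' (a Welch-style standardization).
#'
#' @param data a [LabeledDataset-class] with >= 2 samples per group.
#' @param vertex vertex (column) name or index.
#' @return scalar T statistic.
#' @export
vertexT <- function(data, vertex) {
  g <- .groupSplit(data)
  if (nrow(g$D) < 2L || nrow(g$C) < 2L)
    stop("each group needs >= 2 observations for vertexT")
  xd <- g$D[, vertex]
  xc <- g$C[, vertex]
  den <- sqrt(stats::var(xd) / length(xd) + stats::var(xc) / length(xc))
  if (den == 0) stop("zero pooled variance: T is undefined for vertex ", vertex)
  (mean(xd) - mean(xc)) / den
}

#' Fisher-z differential correlation statistic for one edge
#'
#' \eqn{U_{ij} = (z_{ij}^D - z_{ij}^C) / \sqrt{1/(n_D - 3) + 1/(n_C - 3)}},
#' where \eqn{z_{ij}} are the Fisher transforms of the per-group Pearson
#' correlations of the edge's endpoint columns.
#'
#' @param data a [LabeledDataset-class] with more than 3 samples per group.
#' @param edge length-2 vector of vertex names or column indices.
#' @return scalar U statistic.
#' @export
edgeU <- function(data, edge) {
  g <- .groupSplit(data)
  nD <- nrow(g$D); nC <- nrow(g$C)
  if (nD <= 3L || nC <= 3L)
    stop("each group needs > 3 samples for the Fisher-z denominator")
  sdD <- apply(g$D[, edge, drop = FALSE], 2L, stats::sd)
  sdC <- apply(g$C[, edge, drop = FALSE], 2L, stats::sd)
  if (any(sdD == 0) || any(sdC == 0))
    stop("constant endpoint column within a group: correlation undefined")
  rD <- stats::cor(g$D[, edge[1L]], g$D[, edge[2L]])
  rC <- stats::cor(g$C[, edge[1L]], g$C[, edge[2L]])
  (fisherZ(rD) - fisherZ(rC)) / sqrt(1 / (nD - 3) + 1 / (nC - 3))
}

#' Element-wise network difference measure
#'
#' The vertices-and-edges-wise difference measure
#' \eqn{\mathrm{VEWDM} = \frac1M \sum_i T_i^2 + \frac1K \sum_{(i,j) \in E} U_{ij}^2}:
#' the mean squared standardized vertex mean difference plus the mean
#' squared Fisher-z differential correlation over the K edges of the
#' network, each unordered edge counted once.  Its null distribution is
#' network-specific, so inference uses the permutation engine
#' ([permutationTest()] with \code{statistic = "vewdm"}); no asymptotic
#' p-value is offered.
#'
#' @param data a [LabeledDataset-class] with more than 3 samples per group.
#' @param net a [NetworkSpec-class].
#' @return nonnegative scalar; 0 iff every T and U is 0.
#' @export
vewdmStatistic <- function(data, net) {
  X <- .alignColumns(data, net)
  d <- LabeledDataset(X, groupLabels(data), sampleIds = data@sampleIds)
  Tv <- vapply(seq_len(ncol(X)), function(i) vertexT(d, i), numeric(1))
  e <- edgeMatrix(net)
  out <- mean(Tv^2)
  if (nrow(e) > 0L) {
    U <- vapply(seq_len(nrow(e)), function(k) edgeU(d, e[k, ]), numeric(1))
    out <- out + mean(U^2)
  }
  out
}

#' Permutation test of the element-wise measure
#'
#' Convenience wrapper running [permutationTest()] with
#' \code{statistic = "vewdm"}.
#'
#' @param data a [LabeledDataset-class].
#' @param net a [NetworkSpec-class].
#' @param nPermutations number of label permutations.
#' @param seed optional RNG seed.
#' @return a [TestResult-class] with method \code{"vewdm_permutation"}.
#' @export
vewdmTest <- function(data, net, nPermutations = 1000L, seed = NULL) {
  permutationTest(data, net, statistic = "vewdm",
                  plan = PermutationPlan(nPermutations, seed = seed))
}
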