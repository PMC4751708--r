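#' Construct a PermutationPlan
#'
#' @param nPermutations number of random label permutations Q.
#' @param seed optional integer seed; NULL/NA continues the caller's RNG
#'   stream.
#' @param exhaustive enumerate all \code{choose(N, n_case)} label
#'   assignments instead of sampling.
#' @param exhaustiveCap refuse exhaustive enumeration beyond this many
#'   assignments (default 1e5).
#' @param addOneCorrection report \code{(1 + count)/(1 + Q)} instead of the
#'   plain \code{count/Q} (default off; the plain strict-inequality
#'   estimator is the reference convention, under which a dataset whose
#'   permuted statistics all tie the observed one yields p = 0).
#' @return a [PermutationPlan-class].
#' @export
PermutationPlan <- function(nPermutations = 1000L, seed = NULL,
                            exhaustive = FALSE, exhaustiveCap = 1e5,
                            addOneCorrection = FALSE) {
  if (is.null(seed) || is.na(seed)) seed <- NA_integer_
  new("PermutationPlan", nPermutations = as.integer(nPermutations),
      seed = as.integer(seed), exhaustive = isTRUE(exhaustive),
      exhaustiveCap = as.numeric(exhaustiveCap),
      addOneCorrection = isTRUE(addOneCorrection))
}

#' Randomly permute group labels
#'
#' Uniformly random reassignment of subjects to the two groups with the
#' group sizes kept exactly as in the original data (a permutation of the
#' label vector).
#'
#' @param y integer 0/1 label vector.
#' @return permuted label vector with the same multiset of labels.
#' @export
permuteLabels <- function(y) {
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("labels must be coded exactly 0/1")
  sample(y)
}

# N x Q matrix whose columns are independent random permutations of y.
.permutationMatrix <- function(y, Q) {
  vapply(seq_len(Q), function(i) sample(y), integer(length(y)))
}

# N x C matrix of all label assignments preserving the case count.
.exhaustiveMatrix <- function(y, cap) {
  n <- length(y)
  nCase <- sum(y == 1L)
  total <- choose(n, nCase)
  if (total > cap)
    stop("exhaustive enumeration would need ", format(total),
         " assignments (cap ", format(cap), ")")
  sets <- utils::combn(n, nCase)
  out <- matrix(0L, n, ncol(sets))
  out[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = nCase))] <- 1L
  out
}

# Quadratic-form statistics for every label column of yMat, reusing one
# Cholesky factor of Sigma: Sigma is label-invariant (the label weight sum
# depends only on the group sizes, and cov([X|Z]) not on labels at all),
# so only the score vector D is recomputed per permutation.
.netdifmBatch <- function(W, cholSigma, yMat) {
  Yc <- sweep(yMat, 2L, colMeans(yMat))
  Dall <- crossprod(W, Yc)
  V <- backsolve(cholSigma, Dall, transpose = TRUE)
  colSums(V^2)
}

# Element-wise (VEWDM) statistics for every label column of yMat,
# vectorized through group sums: per-group means, variances and per-edge
# correlations are all linear images of crossprod(X, indicator),
# crossprod(X^2, indicator) and crossprod(x_i * x_j, indicator).
# Correlations at +/-1 are clipped to +/-(1 - 1e-12) before the Fisher
# transform, as in fisherZ().
.vewdmBatch <- function(X, edges, yMat, vertexSubset = NULL) {
  n <- nrow(X)
  nD <- sum(yMat[, 1L] == 1L)
  nC <- n - nD
  stopifnot(nD > 3L, nC > 3L)
  X2 <- X^2
  t1 <- colSums(X)
  t2 <- colSums(X2)
  S1 <- crossprod(X, yMat)          # M x Q case sums
  S2 <- crossprod(X2, yMat)
  mD <- S1 / nD
  mC <- (t1 - S1) / nC
  vD <- (S2 - nD * mD^2) / (nD - 1)
  vC <- ((t2 - S2) - nC * mC^2) / (nC - 1)
  Tstat <- (mD - mC) / sqrt(vD / nD + vC / nC)
  if (!is.null(vertexSubset))
    Tstat <- Tstat[vertexSubset, , drop = FALSE]
  out <- colMeans(Tstat^2)
  if (nrow(edges) > 0L) {
    P <- X[, edges[, 1L], drop = FALSE] * X[, edges[, 2L], drop = FALSE]
    SP <- crossprod(P, yMat)        # K x Q case sums of products
    tP <- colSums(P)
    i <- edges[, 1L]; j <- edges[, 2L]
    covD <- (SP - nD * mD[i, , drop = FALSE] * mD[j, , drop = FALSE]) /
      (nD - 1)
    covC <- ((tP - SP) - nC * mC[i, , drop = FALSE] *
               mC[j, , drop = FALSE]) / (nC - 1)
    rD <- covD / sqrt(vD[i, , drop = FALSE] * vD[j, , drop = FALSE])
    rC <- covC / sqrt(vC[i, , drop = FALSE] * vC[j, , drop = FALSE])
    clip <- function(r) pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
    U <- (atanh(clip(rD)) - atanh(clip(rC))) /
      sqrt(1 / (nD - 3) + 1 / (nC - 3))
    out <- out + colMeans(U^2)
  }
  out
}

#' Permutation test of a network difference statistic
#'
#' Label-permutation inference: (1) compute the statistic on the original
#' labels; (2) randomly reassign subjects to the two groups, keeping the
#' group sizes fixed; (3) recompute the statistic for each of Q permuted
#' label vectors; (4) report
#' \eqn{p = \frac1Q \sum_i I(\mathrm{stat}_i^* > \mathrm{stat})} with a
#' strict inequality (ties count as non-exceedances).  For the
#' quadratic-form statistic the score covariance is computed once and
#' reused across permutations — it is label-invariant — so only the score
#' vector is recomputed, which makes the permutation test roughly as cheap
#' as Q matrix-vector products.
#'
#' @param data a [LabeledDataset-class].
#' @param net a [NetworkSpec-class].
#' @param statistic \code{"netdifm"} (quadratic form) or \code{"vewdm"}
#'   (element-wise measure).
#' @param plan a [PermutationPlan-class].
#' @return a [TestResult-class] with method \code{"netdifm_permutation"}
#'   or \code{"vewdm_permutation"}; \code{nPermutations} records Q (or the
#'   number of enumerated assignments when \code{exhaustive = TRUE}).
#' @examples
#' net <- NetworkSpec(c("A", "B", "C"),
#'                    rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' scn <- makeScenario(net, n = 60)
#' set.seed(1)
#' d <- simulateCaseControl(scn)
#' permutationTest(d, net, "netdifm", PermutationPlan(199, seed = 7))
#' @export
permutationTest <- function(data, net,
                            statistic = c("netdifm", "vewdm"),
                            plan = PermutationPlan()) {
  .permTestCore(data, net, match.arg(statistic), plan)
}

# Shared engine behind permutationTest() and vertexSubnetworkTest():
# focalVertex, when given, restricts the vertex block of either statistic
# to the focal vertex (the edge block is the star's incident edges).
.permTestCore <- function(data, net, statistic, plan, focalVertex = NULL) {
  stopifnot(is(plan, "PermutationPlan"))
  if (!is.na(plan@seed)) set.seed(plan@seed)
  X <- .alignColumns(data, net)
  y <- groupLabels(data)
  e <- edgeMatrix(net)

  yMat <- if (plan@exhaustive) .exhaustiveMatrix(y, plan@exhaustiveCap)
          else .permutationMatrix(y, plan@nPermutations)
  Q <- ncol(yMat)

  if (statistic == "netdifm") {
    dec <- scoreCovariance(data, net)
    idx <- if (is.null(focalVertex)) seq_len(nrow(dec@Sigma))
           else .starSelection(net, focalVertex)
    D <- c(dec@Dvertex, dec@Dedge)[idx]
    S <- dec@Sigma[idx, idx, drop = FALSE]
    observed <- .quadForm(S, D)     # direct solver incl. condition guard
    W <- .workingMatrix(X, e)[, idx, drop = FALSE]
    permStats <- .netdifmBatch(W, chol(S), yMat)
    method <- "netdifm_permutation"
  } else {
    vset <- if (is.null(focalVertex)) NULL
            else match(focalVertex, vertexNames(net))
    observed <- if (is.null(vset)) vewdmStatistic(data, net)
                else drop(.vewdmBatch(X, e, matrix(y, ncol = 1L), vset))
    permStats <- .vewdmBatch(X, e, yMat, vset)
    method <- "vewdm_permutation"
  }
  count <- sum(permStats > observed)
  p <- if (plan@addOneCorrection) (1 + count) / (1 + Q) else count / Q
  new("TestResult", statistic = observed, df = NA_integer_, pValue = p,
      method = method, nPermutations = as.integer(Q), seed = plan@seed)
}
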