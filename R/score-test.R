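#' Per-vertex score statistics
#'
#' The vertex score \eqn{D_i^V = \sum_{l=1}^N (Y_l - \bar Y)\, x_{li}}
#' measures the contribution of vertex \eqn{x_i} to the group difference:
#' it is the score statistic for the vertex's mean level under a
#' case/control comparison.
#'
#' @param data a [LabeledDataset-class].
#' @param net optional [NetworkSpec-class]; when supplied, columns are
#'   aligned to the network's vertex order.
#' @return named numeric vector of length M.
#' @export
vertexScores <- function(data, net = NULL) {
  X <- if (is.null(net)) dataMatrix(data) else .alignColumns(data, net)
  y <- groupLabels(data)
  d <- as.vector(crossprod(X, y - mean(y)))
  names(d) <- colnames(X)
  d
}

#' Per-edge score statistics
#'
#' The edge score
#' \eqn{D_k^E = \sum_{l=1}^N (Y_l - \bar Y)(x_{li} - \bar x_i)(x_{lj} - \bar x_j)}
#' for edge \eqn{k = (i, j)} measures the contribution of the connection
#' strength between \eqn{x_i} and \eqn{x_j}: it is a label-weighted sum of
#' centered cross-products, i.e. a score statistic for the covariance of
#' the two endpoints.  Means \eqn{\bar x_i} are pooled over all N samples.
#'
#' @param data a [LabeledDataset-class].
#' @param net a [NetworkSpec-class]; scores are returned in canonical
#'   edge order.
#' @return named numeric vector of length K.
#' @export
edgeScores <- function(data, net) {
  X <- .alignColumns(data, net)
  y <- groupLabels(data)
  Z <- .edgeProducts(X, edgeMatrix(net))
  d <- as.vector(crossprod(Z, y - mean(y)))
  names(d) <- edgeNames(net)
  d
}

# Centered cross-product columns Z_k = (X_i - mean) * (X_j - mean), the
# working variables whose scores are the edge scores.
.edgeProducts <- function(X, edges) {
  Xc <- sweep(X, 2L, colMeans(X))
  Z <- Xc[, edges[, 1L], drop = FALSE] * Xc[, edges[, 2L], drop = FALSE]
  Z
}

# Working-variable matrix W = [X | Z], N x (M+K).
.workingMatrix <- function(X, edges) {
  cbind(X, .edgeProducts(X, edges))
}

#' Score vectors and estimated covariance of the network difference score
#'
#' Assembles the concatenated score vector \eqn{D = (D^V, D^E)} and its
#' estimated covariance \eqn{\Sigma}, built from the blocks
#' \eqn{\Sigma_V}, \eqn{\Sigma_E} and \eqn{\Sigma_{VE}} with entries
#' \eqn{\sigma_{pq} = \sum_l (Y_l-\bar Y)^2\, \mathrm{cov}(W_p, W_q)},
#' where the working variables \eqn{W} are the data columns \eqn{X} and
#' the centered cross-products \eqn{Z}.  Because the cov terms do not
#' depend on the sample index, the whole matrix factorizes as
#' \eqn{\Sigma = \sum_l (Y_l - \bar Y)^2 \times \mathrm{cov}([X\,|\,Z])};
#' this factorization is what makes \eqn{\Sigma} invariant under label
#' permutation and is exploited by the permutation engine.
#'
#' @param data a [LabeledDataset-class] with N >= 3.
#' @param net a [NetworkSpec-class].
#' @return a [ScoreDecomposition-class].
#' @export
scoreCovariance <- function(data, net) {
  X <- .alignColumns(data, net)
  if (nrow(X) < 3L) stop("N >= 3 required to estimate the score covariance")
  y <- groupLabels(data)
  e <- edgeMatrix(net)
  W <- .workingMatrix(X, e)
  lws <- sum((y - mean(y))^2)
  Sigma <- lws * stats::cov(W)
  yc <- y - mean(y)
  d <- as.vector(crossprod(W, yc))
  m <- ncol(X)
  new("ScoreDecomposition",
      Dvertex = d[seq_len(m)],
      Dedge = if (nrow(e)) d[m + seq_len(nrow(e))] else numeric(0),
      Sigma = unname(Sigma), labelWeightSum = lws,
      vertexNames = vertexNames(net), edgeNames = edgeNames(net))
}

#' @rdname ScoreDecomposition-accessors
#' @export
setMethod("scoreVector", "ScoreDecomposition",
          function(object) {
  stats::setNames(c(object@Dvertex, object@Dedge),
                  c(object@vertexNames, object@edgeNames))
})

#' Accessors for ScoreDecomposition
#'
#' @param object a [ScoreDecomposition-class].
#' @return \code{scoreVector}: the concatenated (M+K) score vector D;
#'   \code{covarianceMatrix}: its estimated covariance Sigma.
#' @name ScoreDecomposition-accessors
#' @aliases scoreVector covarianceMatrix
NULL

#' @rdname ScoreDecomposition-accessors
#' @export
setMethod("covarianceMatrix", "ScoreDecomposition",
          function(object) object@Sigma)

setMethod("show", "ScoreDecomposition", function(object) {
  cat("ScoreDecomposition: M =", length(object@Dvertex),
      "vertex scores, K =", length(object@Dedge), "edge scores\n")
  cat("  label weight sum:", format(object@labelWeightSum), "\n")
})

# Quadratic form D' Sigma^{-1} D via a linear solve (no explicit inverse).
# The condition-number guard mirrors the method's own limitation: the
# statistic is undefined when Sigma is (numerically) singular, and the
# documented remedy is to simplify the network first.
.quadForm <- function(Sigma, D, solver = c("direct", "pseudoinverse", "ridge"),
                      ridgeLambda = NULL, conditionCap = 1e12) {
  solver <- match.arg(solver)
  if (solver == "direct") {
    rc <- rcond(Sigma)
    if (!is.finite(rc) || rc < 1 / conditionCap)
      stop("score covariance is numerically singular (reciprocal condition ",
           "number ", format(rc), "); the network difference statistic is ",
           "undefined for a non-invertible covariance. Simplify the network ",
           "first, e.g. pruneEdges() to remove weakly correlated edges, or ",
           "use solver = 'pseudoinverse' or 'ridge'.")
    return(drop(crossprod(D, solve(Sigma, D))))
  }
  if (solver == "pseudoinverse")
    return(drop(crossprod(D, MASS::ginv(Sigma) %*% D)))
  if (is.null(ridgeLambda))
    stop("solver = 'ridge' requires ridgeLambda")
  S <- Sigma + diag(ridgeLambda * mean(diag(Sigma)), nrow(Sigma))
  drop(crossprod(D, solve(S, D)))
}

#' The network difference measure (quadratic-form score statistic)
#'
#' Computes \eqn{\mathrm{NetDifM} = D^T \Sigma^{-1} D} from a
#' [ScoreDecomposition-class].  The default solver performs a linear solve
#' and refuses ill-conditioned covariances (reciprocal condition number
#' below 1e-12); \code{pseudoinverse} (Moore-Penrose) and \code{ridge}
#' (adds \code{ridgeLambda * mean(diag(Sigma))} to the diagonal) are
#' opt-in fallbacks for the singular case.
#'
#' @param dec a [ScoreDecomposition-class].
#' @param solver one of \code{"direct"}, \code{"pseudoinverse"},
#'   \code{"ridge"}.
#' @param ridgeLambda relative ridge penalty (required for
#'   \code{solver = "ridge"}).
#' @return nonnegative scalar statistic.
#' @export
netDifMStatistic <- function(dec, solver = c("direct", "pseudoinverse",
                                             "ridge"),
                             ridgeLambda = NULL) {
  D <- c(dec@Dvertex, dec@Dedge)
  .quadForm(dec@Sigma, D, solver = match.arg(solver),
            ridgeLambda = ridgeLambda)
}

#' Asymptotic network difference test
#'
#' Tests the null hypothesis that the two groups share the same weighted
#' network (identical vertex levels and identical connection strengths)
#' using the quadratic-form score statistic, which for large samples has a
#' central chi-square distribution with M + K degrees of freedom under the
#' null.
#'
#' @param data a [LabeledDataset-class].
#' @param net a [NetworkSpec-class].
#' @param solver,ridgeLambda passed to [netDifMStatistic()].
#' @return a [TestResult-class] with method \code{"netdifm_asymptotic"}.
#' @examples
#' net <- NetworkSpec(c("A", "B", "C"),
#'                    rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' scn <- makeScenario(net, n = 100)
#' set.seed(1)
#' d <- simulateCaseControl(scn)
#' netDifMTest(d, net)
#' @export
netDifMTest <- function(data, net, solver = "direct", ridgeLambda = NULL) {
  dec <- scoreCovariance(data, net)
  stat <- netDifMStatistic(dec, solver = solver, ridgeLambda = ridgeLambda)
  df <- vertexCount(net) + edgeCount(net)
  new("TestResult", statistic = stat, df = as.integer(df),
      pValue = stats::pchisq(stat, df = df, lower.tail = FALSE),
      method = "netdifm_asymptotic", nPermutations = NA_integer_,
      seed = NA_integer_)
}

# Positions of the focal vertex's score and its incident edges' scores
# within the star subnetwork's concatenated (M_star + K_star) score vector.
.starSelection <- function(sub, focalName) {
  focal <- match(focalName, vertexNames(sub))
  c(focal, vertexCount(sub) + seq_len(edgeCount(sub)))
}

#' Per-vertex subnetwork test
#'
#' Localizes the network comparison to one vertex by treating the vertex
#' together with its connected edges as a network of its own: the score
#' vector is restricted to the focal vertex's score and the scores of its
#' incident edges (the neighbors' own vertex levels are not tested, so a
#' signal at one vertex does not bleed into its neighbors' tests).  For
#' the asymptotic method the degrees of freedom are \eqn{1 + d} for a
#' degree-\eqn{d} vertex.
#'
#' @param data a [LabeledDataset-class].
#' @param net a [NetworkSpec-class].
#' @param vertex focal vertex name or index; must have degree >= 1.
#' @param method \code{"asymptotic"} (chi-square), \code{"permutation"}
#'   (permutation null of the quadratic form) or \code{"vewdm"}
#'   (permutation null of the element-wise measure, with the vertex term
#'   restricted to the focal vertex).
#' @param nPermutations,seed permutation settings (ignored for
#'   \code{"asymptotic"}).
#' @return a [TestResult-class].
#' @export
vertexSubnetworkTest <- function(data, net, vertex,
                                 method = c("asymptotic", "permutation",
                                            "vewdm"),
                                 nPermutations = 1000L, seed = NULL) {
  method <- match.arg(method)
  sub <- incidentSubnetwork(net, vertex)
  if (edgeCount(sub) == 0L)
    stop("vertex '", vertex, "' has degree 0: no incident edges, ",
         "subnetwork is untestable")
  focalName <- vertexNames(net)[.resolveVertex(net, vertex)]
  Xsub <- .alignColumns(data, sub)
  dsub <- LabeledDataset(Xsub, groupLabels(data),
                         sampleIds = data@sampleIds)
  if (method == "asymptotic") {
    dec <- scoreCovariance(dsub, sub)
    sel <- .starSelection(sub, focalName)
    D <- c(dec@Dvertex, dec@Dedge)[sel]
    S <- dec@Sigma[sel, sel, drop = FALSE]
    stat <- .quadForm(S, D)
    df <- length(sel)
    return(new("TestResult", statistic = stat, df = as.integer(df),
               pValue = stats::pchisq(stat, df = df, lower.tail = FALSE),
               method = "netdifm_asymptotic",
               nPermutations = NA_integer_, seed = NA_integer_))
  }
  .permTestCore(dsub, sub,
                statistic = if (method == "vewdm") "vewdm" else "netdifm",
                plan = PermutationPlan(nPermutations, seed = seed),
                focalVertex = focalName)
}

#' Accessors for TestResult
#'
#' @param object a [TestResult-class].
#' @return \code{testStatistic}, \code{pValue}: numeric scalars;
#'   \code{degreesOfFreedom}: integer (NA for permutation methods);
#'   \code{methodLabel}: character.
#' @name TestResult-accessors
#' @aliases testStatistic pValue degreesOfFreedom methodLabel
NULL

#' @rdname TestResult-accessors
#' @export
setMethod("testStatistic", "TestResult", function(object) object@statistic)

#' @rdname TestResult-accessors
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @rdname TestResult-accessors
#' @export
setMethod("degreesOfFreedom", "TestResult", function(object) object@df)

#' @rdname TestResult-accessors
#' @export
setMethod("methodLabel", "TestResult", function(object) object@method)

setMethod("show", "TestResult", function(object) {
  cat("Network difference test (", object@method, ")\n", sep = "")
  cat("  statistic =", format(object@statistic, digits = 6))
  if (!is.na(object@df)) cat(", df =", object@df)
  cat("\n  p-value   =", format(object@pValue, digits = 4), "\n")
  if (!is.na(object@nPermutations))
    cat("  permutations:", object@nPermutations,
        if (!is.na(object@seed)) paste0("(seed ", object@seed, ")"), "\n")
})
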