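#' @import methods
#' @importFrom stats cov cor var pchisq sd rnorm setNames
NULL

#' NetworkSpec: an undirected network topology with canonical edge indexing
#'
#' Represents the fixed topology of a weighted biological network: M named
#' vertices and K undirected edges.  Edges are stored as index pairs
#' \code{(i, j)} with \code{i < j}, sorted lexicographically, so that the
#' positions \code{M+1, ..., M+K} of the concatenated score vector are
#' reproducible across runs and platforms.
#'
#' @slot vertexNames character vector of M unique vertex identifiers.
#' @slot edges integer matrix with K rows and 2 columns; each row is an
#'   edge \code{(i, j)} with \code{1 <= i < j <= M}, rows sorted by
#'   \code{(i, j)} and unique.
#'
#' @seealso [NetworkSpec()], [loadEdgeList()], [incidentSubnetwork()],
#'   [pruneEdges()]
#' @export
setClass("NetworkSpec",
  representation(vertexNames = "character", edges = "matrix"),
  prototype(vertexNames = character(0),
            edges = matrix(integer(0), ncol = 2L)))

setValidity("NetworkSpec", function(object) {
  v <- object@vertexNames
  e <- object@edges
  msgs <- character(0)
  if (anyDuplicated(v)) msgs <- c(msgs, "vertex names must be unique")
  if (ncol(e) != 2L) msgs <- c(msgs, "edges must have two columns")
  if (!is.integer(e)) msgs <- c(msgs, "edges must be an integer matrix")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > length(v)))
      msgs <- c(msgs, "edge endpoints must index into vertexNames")
    else {
      if (any(e[, 1L] >= e[, 2L]))
        msgs <- c(msgs, "edges must satisfy i < j (no self-loops)")
      o <- order(e[, 1L], e[, 2L])
      if (!all(o == seq_len(nrow(e))))
        msgs <- c(msgs, "edges must be sorted lexicographically by (i, j)")
      if (anyDuplicated(paste(e[, 1L], e[, 2L])))
        msgs <- c(msgs, "duplicate edges are not allowed")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' LabeledDataset: a two-group continuous data matrix
#'
#' The sample unit consumed by every statistic in the package: an N x M
#' matrix of continuous vertex measurements (rows are individuals, columns
#' are network vertices, e.g. gene-level expression values or per-gene
#' principal-component scores) together with binary group labels
#' (1 = case, 0 = control).
#'
#' @slot X numeric matrix, N samples x M vertices, no missing values;
#'   column names are the vertex names.
#' @slot y integer vector of length N with values exactly 0 or 1; both
#'   labels must be present.
#' @slot sampleIds character vector of length N.
#'
#' @seealso [LabeledDataset()], [vertexScores()], [netDifMTest()]
#' @export
setClass("LabeledDataset",
  representation(X = "matrix", y = "integer", sampleIds = "character"))

setValidity("LabeledDataset", function(object) {
  X <- object@X
  y <- object@y
  msgs <- character(0)
  if (!is.numeric(X)) msgs <- c(msgs, "X must be a numeric matrix")
  if (anyNA(X)) msgs <- c(msgs, "X must not contain missing values (resolve missingness upstream)")
  if (is.null(colnames(X))) msgs <- c(msgs, "X must carry vertex names as column names")
  else if (anyDuplicated(colnames(X))) msgs <- c(msgs, "vertex (column) names must be unique")
  if (length(y) != nrow(X)) msgs <- c(msgs, "length(y) must equal nrow(X)")
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be coded exactly 0/1 (no silent recoding)")
  else if (sum(y == 1L) < 1L || sum(y == 0L) < 1L)
    msgs <- c(msgs, "both groups (cases and controls) must be present")
  if (length(object@sampleIds) != nrow(X))
    msgs <- c(msgs, "sampleIds must have one entry per row of X")
  if (length(msgs)) msgs else TRUE
})

#' ScoreDecomposition: score vectors and their estimated covariance
#'
#' Internal decomposition of the network difference measure: the length-M
#' vertex score vector, the length-K edge score vector, and the estimated
#' (M+K) x (M+K) covariance matrix of the concatenated score vector,
#' assembled from blocks Sigma_V, Sigma_E and Sigma_VE.
#'
#' @slot Dvertex numeric length-M vertex scores.
#' @slot Dedge numeric length-K edge scores (in canonical edge order).
#' @slot Sigma numeric (M+K) x (M+K) symmetric covariance estimate.
#' @slot labelWeightSum scalar \eqn{\sum_l (Y_l - \bar Y)^2}.
#' @slot vertexNames,edgeNames identifiers for the score positions.
#'
#' @seealso [scoreCovariance()], [netDifMStatistic()]
#' @export
setClass("ScoreDecomposition",
  representation(Dvertex = "numeric", Dedge = "numeric", Sigma = "matrix",
                 labelWeightSum = "numeric", vertexNames = "character",
                 edgeNames = "character"))

setValidity("ScoreDecomposition", function(object) {
  m <- length(object@Dvertex)
  k <- length(object@Dedge)
  S <- object@Sigma
  msgs <- character(0)
  if (nrow(S) != m + k || ncol(S) != m + k)
    msgs <- c(msgs, "Sigma must be (M+K) x (M+K)")
  else {
    tol <- 1e-8 * max(1, max(abs(S)))
    if (max(abs(S - t(S))) > tol) msgs <- c(msgs, "Sigma must be symmetric")
  }
  if (length(object@labelWeightSum) != 1L || object@labelWeightSum < 0)
    msgs <- c(msgs, "labelWeightSum must be a nonnegative scalar")
  if (length(msgs)) msgs else TRUE
})

#' TestResult: the outcome of a network difference test
#'
#' @slot statistic nonnegative test statistic value.
#' @slot df degrees of freedom (M+K for the asymptotic test, NA for
#'   permutation-only methods).
#' @slot pValue p-value in [0, 1].
#' @slot method one of \code{"netdifm_asymptotic"},
#'   \code{"netdifm_permutation"}, \code{"vewdm_permutation"}.
#' @slot nPermutations number of permutations used (NA if asymptotic).
#' @slot seed RNG seed recorded for permutation methods (NA otherwise).
#'
#' @seealso [netDifMTest()], [permutationTest()]
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "integer", pValue = "numeric",
                 method = "character", nPermutations = "integer",
                 seed = "integer"))

setValidity("TestResult", function(object) {
  msgs <- character(0)
  if (length(object@statistic) != 1L || !is.finite(object@statistic) ||
      object@statistic < 0)
    msgs <- c(msgs, "statistic must be a nonnegative finite scalar")
  if (length(object@pValue) != 1L || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (!object@method %in% c("netdifm_asymptotic", "netdifm_permutation",
                            "vewdm_permutation"))
    msgs <- c(msgs, "unknown method label")
  if (length(msgs)) msgs else TRUE
})

#' PermutationPlan: configuration of the label-permutation engine
#'
#' @slot nPermutations number of random label permutations Q (>= 1).
#' @slot seed integer RNG seed, or NA to continue the current RNG stream.
#' @slot exhaustive if TRUE, enumerate all label assignments that preserve
#'   the group sizes instead of sampling (only allowed when
#'   \code{choose(N, n_case)} does not exceed \code{exhaustiveCap}).
#' @slot exhaustiveCap largest number of assignments that may be enumerated.
#' @slot addOneCorrection if TRUE, report \code{(1 + count)/(1 + Q)} instead
#'   of the plain \code{count/Q} estimator (default off; the plain strict
#'   ">" estimator is the reference convention).
#'
#' @seealso [PermutationPlan()], [permutationTest()]
#' @export
setClass("PermutationPlan",
  representation(nPermutations = "integer", seed = "integer",
                 exhaustive = "logical", exhaustiveCap = "numeric",
                 addOneCorrection = "logical"))

setValidity("PermutationPlan", function(object) {
  msgs <- character(0)
  if (object@nPermutations < 1L)
    msgs <- c(msgs, "nPermutations must be >= 1")
  if (object@exhaustiveCap < 1)
    msgs <- c(msgs, "exhaustiveCap must be positive")
  if (length(msgs)) msgs else TRUE
})

#' SimulationScenario: one null or alternative simulation setting
#'
#' Defines a two-group multivariate normal generating model on a network:
#' per-group mean vectors and per-edge correlations, group sizes, and an
#' optional marginal exponential transform used in the robustness study.
#' The implied covariance matrices have \code{diagVar} on the diagonal,
#' the per-edge correlation at edge positions and 0 elsewhere, and must be
#' positive definite.
#'
#' @slot net a [NetworkSpec-class].
#' @slot muCase,muControl length-M mean vectors.
#' @slot betaCase,betaControl length-K per-edge correlation values, in
#'   canonical edge order.
#' @slot nCase,nControl group sizes.
#' @slot transform one of \code{"none"}, \code{"exp_subset"},
#'   \code{"exp_all"}: elementwise exponential applied columnwise after the
#'   MVN draw.
#' @slot transformVertices integer indices of the transformed vertices when
#'   \code{transform == "exp_subset"}.
#' @slot diagVar length-M per-vertex variances (default all 1).
#'
#' @seealso [SimulationScenario()], [makeScenario()],
#'   [simulateCaseControl()], [estimateRejectionRate()]
#' @export
setClass("SimulationScenario",
  representation(net = "NetworkSpec", muCase = "numeric",
                 muControl = "numeric", betaCase = "numeric",
                 betaControl = "numeric", nCase = "integer",
                 nControl = "integer", transform = "character",
                 transformVertices = "integer", diagVar = "numeric"))

setValidity("SimulationScenario", function(object) {
  m <- length(object@net@vertexNames)
  k <- nrow(object@net@edges)
  msgs <- character(0)
  if (length(object@muCase) != m || length(object@muControl) != m)
    msgs <- c(msgs, "mean vectors must have one entry per vertex")
  if (length(object@betaCase) != k || length(object@betaControl) != k)
    msgs <- c(msgs, "beta vectors must have one entry per edge")
  if (length(object@diagVar) != m || any(object@diagVar <= 0))
    msgs <- c(msgs, "diagVar must be positive, one entry per vertex")
  if (object@nCase < 1L || object@nControl < 1L)
    msgs <- c(msgs, "both group sizes must be >= 1")
  if (!object@transform %in% c("none", "exp_subset", "exp_all"))
    msgs <- c(msgs, "transform must be none, exp_subset or exp_all")
  if (object@transform == "exp_subset" &&
      (length(object@transformVertices) == 0L ||
       any(object@transformVertices < 1L | object@transformVertices > m)))
    msgs <- c(msgs, "transformVertices must be valid vertex indices")
  if (length(msgs) == 0L) {
    for (beta in list(object@betaCase, object@betaControl)) {
      sig <- try(buildSigma(object@net, beta, object@diagVar), silent = TRUE)
      if (inherits(sig, "try-error"))
        msgs <- c(msgs, attr(sig, "condition")$message)
    }
  }
  if (length(msgs)) msgs else TRUE
})
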