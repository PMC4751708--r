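#' Network-structured covariance matrix
#'
#' Builds the M x M covariance matrix used by the simulation model:
#' \code{diagVar} on the diagonal, the per-edge value \eqn{\beta_{ij}} at
#' positions where the network has an edge, and 0 elsewhere.  The result
#' must be positive definite; no silent repair is attempted.
#'
#' @param net a [NetworkSpec-class].
#' @param beta numeric vector with one value per edge (recycled if
#'   length 1), in canonical edge order.
#' @param diagVar per-vertex variances (default 1).
#' @return M x M symmetric positive-definite matrix.
#' @examples
#' net <- NetworkSpec(c("a", "b"), rbind(c(1L, 2L)))
#' buildSigma(net, 0.3)  # eigenvalues 1.3 and 0.7
#' @export
buildSigma <- function(net, beta, diagVar = 1) {
  m <- vertexCount(net)
  k <- edgeCount(net)
  if (length(beta) == 1L) beta <- rep(beta, k)
  if (length(beta) != k) stop("need one beta per edge (", k, ")")
  if (length(diagVar) == 1L) diagVar <- rep(diagVar, m)
  sig <- diag(diagVar, m)
  e <- edgeMatrix(net)
  if (k > 0L) {
    sig[e] <- beta
    sig[e[, c(2L, 1L), drop = FALSE]] <- beta
  }
  ev <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop("covariance is not positive definite (min eigenvalue ",
         format(ev), ")")
  dimnames(sig) <- list(vertexNames(net), vertexNames(net))
  sig
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random connected network of given size
#'
#' Deterministic (seeded) generator of a connected undirected graph with
#' exactly M vertices and K edges: a uniformly random spanning tree
#' attachment (each new vertex joins a uniformly chosen earlier vertex)
#' plus K - M + 1 distinct extra edges sampled without replacement from
#' the remaining vertex pairs.  Used to instantiate benchmark topologies
#' of a given scale, e.g. 10 vertices / 21 edges or 20 vertices /
#' 45 edges, when only the scale (not the adjacency) is prescribed.
#'
#' @param M vertex count (vertices are named \code{v1..vM}).
#' @param K edge count; must satisfy \code{M - 1 <= K <= M(M-1)/2}.
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return a [NetworkSpec-class].
#' @export
randomConnectedNetwork <- function(M, K, seed) {
  if (K < M - 1 || K > M * (M - 1) / 2)
    stop("K must lie in [M-1, M(M-1)/2]")
  .withSeed(seed, {
    ord <- sample.int(M)
    tree <- t(vapply(2:M, function(t)
      c(ord[sample.int(t - 1L, 1L)], ord[t]), integer(2)))
    key <- function(e) {
      i <- pmin(e[, 1L], e[, 2L]); j <- pmax(e[, 1L], e[, 2L])
      (i - 1L) * M + j
    }
    all <- which(upper.tri(matrix(0, M, M)))
    allKey <- (row(matrix(0, M, M))[all] - 1L) * M +
      col(matrix(0, M, M))[all]
    pool <- setdiff(allKey, key(tree))
    extra <- sample(pool, K - (M - 1L))
    i <- ((c(key(tree), extra) - 1L) %/% M) + 1L
    j <- ((c(key(tree), extra) - 1L) %% M) + 1L
    j[j == 0L] <- M  # unreachable given i<j keys, kept as a guard
    NetworkSpec(paste0("v", seq_len(M)), cbind(i, j), quiet = TRUE)
  })
}

#' Draw one group from the simulation model
#'
#' n independent draws from \eqn{N_M(\mu, \Sigma)}, optionally followed by
#' an elementwise exponential transform on a subset of vertex columns
#' (used in the robustness study to create skewed, non-normal marginals).
#'
#' @param mu length-M mean vector.
#' @param sigma M x M positive-definite covariance.
#' @param n number of samples.
#' @param transform \code{"none"}, \code{"exp_subset"} or \code{"exp_all"}.
#' @param transformVertices columns transformed when
#'   \code{transform = "exp_subset"}.
#' @return n x M numeric matrix (column names from \code{sigma}).
#' @export
simulateGroup <- function(mu, sigma, n, transform = "none",
                          transformVertices = integer(0)) {
  X <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  if (n == 1L) X <- matrix(X, nrow = 1L)
  cols <- switch(transform,
                 none = integer(0),
                 exp_all = seq_len(ncol(X)),
                 exp_subset = transformVertices,
                 stop("unknown transform: ", transform))
  if (length(cols)) X[, cols] <- exp(X[, cols])
  colnames(X) <- colnames(sigma)
  X
}

#' Construct a SimulationScenario
#'
#' Low-level constructor; see [makeScenario()] for the convenience
#' interface used to set up null and alternative settings.
#'
#' @param net a [NetworkSpec-class].
#' @param muCase,muControl length-M mean vectors.
#' @param betaCase,betaControl per-edge correlations (scalars recycled).
#' @param nCase,nControl group sizes.
#' @param transform,transformVertices marginal transform, see
#'   [simulateGroup()].
#' @param diagVar per-vertex variances (default 1).
#' @return a [SimulationScenario-class].
#' @export
SimulationScenario <- function(net, muCase, muControl, betaCase,
                               betaControl, nCase, nControl,
                               transform = "none",
                               transformVertices = integer(0),
                               diagVar = 1) {
  m <- vertexCount(net); k <- edgeCount(net)
  expand <- function(x, len) if (length(x) == 1L) rep(x, len) else x
  new("SimulationScenario", net = net,
      muCase = expand(muCase, m), muControl = expand(muControl, m),
      betaCase = expand(betaCase, k), betaControl = expand(betaControl, k),
      nCase = as.integer(nCase), nControl = as.integer(nControl),
      transform = transform,
      transformVertices = as.integer(transformVertices),
      diagVar = expand(diagVar, m))
}

#' Convenience scenario builder
#'
#' Sets up the study designs of the simulation module on a given network:
#' a null setting (identical mean vectors and identical edge correlations
#' in both groups) or one of three alternatives — mean shifts at selected
#' vertices (\code{"vertex"}), correlation shifts at selected edges
#' (\code{"edge"}), or both (\code{"both"}).  Defaults mirror the
#' benchmark design: baseline correlation 0.3 on every edge, two vertices
#' shifted by +0.2, three edges shifted by (-0.2, +0.2, +0.2), total
#' sample size split equally between the groups, and shifted positions
#' chosen reproducibly by \code{selectionSeed} (subject to both group
#' covariances remaining positive definite).
#'
#' @param net a [NetworkSpec-class].
#' @param type \code{"null"}, \code{"vertex"}, \code{"edge"} or
#'   \code{"both"}.
#' @param n total sample size, split as equally as possible between the
#'   groups (override with \code{nCase}/\code{nControl}).
#' @param nCase,nControl explicit group sizes.
#' @param baselineBeta baseline correlation on every edge (default 0.3).
#' @param vertexShifts named or unnamed numeric vector of case-minus-control
#'   mean shifts; unnamed values are placed at vertices drawn with
#'   \code{selectionSeed}.
#' @param edgeShifts numeric vector of case-minus-control correlation
#'   shifts; placed at edges drawn with \code{selectionSeed}.
#' @param transform,transformVertices marginal transform for the
#'   robustness study; \code{transformVertices = NULL} with
#'   \code{transform = "exp_subset"} picks \code{ceiling(M/2)} vertices
#'   with \code{selectionSeed}.
#' @param selectionSeed seed fixing which vertices/edges are shifted or
#'   transformed (default 42).
#' @return a [SimulationScenario-class].
#' @export
makeScenario <- function(net, type = c("null", "vertex", "edge", "both"),
                         n = 200L, nCase = NULL, nControl = NULL,
                         baselineBeta = 0.3,
                         vertexShifts = c(0.2, 0.2),
                         edgeShifts = c(-0.2, 0.2, 0.2),
                         transform = "none", transformVertices = NULL,
                         selectionSeed = 42L) {
  type <- match.arg(type)
  m <- vertexCount(net); k <- edgeCount(net)
  if (is.null(nCase)) nCase <- floor(n / 2)
  if (is.null(nControl)) nControl <- n - nCase
  muC <- rep(0, m); muD <- muC
  betaC <- rep(baselineBeta, k); betaD <- betaC
  picks <- .withSeed(selectionSeed, list(
    v = sample.int(m, min(length(vertexShifts), m)),
    e = sample.int(k, min(length(edgeShifts), k)),
    t = sample.int(m, ceiling(m / 2))))
  if (type %in% c("vertex", "both")) {
    idx <- if (!is.null(names(vertexShifts)))
      vapply(names(vertexShifts), function(nm) .resolveVertex(net, nm),
             integer(1))
    else picks$v
    muD[idx] <- muD[idx] + vertexShifts
  }
  if (type %in% c("edge", "both")) {
    betaD[picks$e] <- betaD[picks$e] + edgeShifts
  }
  if (transform == "exp_subset" && is.null(transformVertices))
    transformVertices <- picks$t
  SimulationScenario(net, muCase = muD, muControl = muC,
                     betaCase = betaD, betaControl = betaC,
                     nCase = nCase, nControl = nControl,
                     transform = transform,
                     transformVertices = transformVertices %||% integer(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Is a scenario a null setting?
#'
#' TRUE iff the case and control mean vectors and per-edge correlations
#' coincide elementwise (the marginal transform, applied identically to
#' both groups, does not break the null).
#'
#' @param scn a [SimulationScenario-class].
#' @return logical.
#' @export
isNullScenario <- function(scn) {
  identical(scn@muCase, scn@muControl) &&
    identical(scn@betaCase, scn@betaControl)
}

setMethod("show", "SimulationScenario", function(object) {
  cat("SimulationScenario on", vertexCount(object@net), "vertices /",
      edgeCount(object@net), "edges\n")
  cat("  groups: nCase =", object@nCase, ", nControl =", object@nControl,
      "\n")
  cat("  setting:", if (isNullScenario(object)) "null (H0)"
      else "alternative (H1)", "; transform:", object@transform, "\n")
})

#' Simulate one case/control dataset from a scenario
#'
#' Stacks an nCase-sample case group and an nControl-sample control group
#' drawn from the scenario's two multivariate normal models (cases first,
#' labels 1/0), applying the scenario's marginal transform to both groups.
#'
#' @param scn a [SimulationScenario-class].
#' @return a [LabeledDataset-class] with N = nCase + nControl rows.
#' @export
simulateCaseControl <- function(scn) {
  sigD <- buildSigma(scn@net, scn@betaCase, scn@diagVar)
  sigC <- buildSigma(scn@net, scn@betaControl, scn@diagVar)
  XD <- simulateGroup(scn@muCase, sigD, scn@nCase, scn@transform,
                      scn@transformVertices)
  XC <- simulateGroup(scn@muControl, sigC, scn@nControl, scn@transform,
                      scn@transformVertices)
  LabeledDataset(rbind(XD, XC),
                 c(rep(1L, scn@nCase), rep(0L, scn@nControl)))
}

#' Monte Carlo rejection rate of a test under a scenario
#'
#' Repeatedly simulates datasets from the scenario and applies the chosen
#' test, reporting the fraction of replicates with p-value below
#' \code{alpha}: the empirical type I error rate when the scenario is a
#' null setting, the empirical power otherwise.
#'
#' @param scn a [SimulationScenario-class].
#' @param method \code{"netdifm_asymptotic"}, \code{"netdifm_permutation"}
#'   or \code{"vewdm_permutation"}.
#' @param alpha nominal level (default 0.05).
#' @param nReplicates number of simulated datasets (default 1000).
#' @param nPermutations permutations per replicate for the permutation
#'   methods (default 1000).
#' @param seed integer seed for the whole experiment.
#' @return list with elements \code{rate}, \code{se} (binomial standard
#'   error), \code{pValues} (per-replicate diagnostics),
#'   \code{statistics}, \code{nReplicates}, \code{method}, \code{alpha},
#'   \code{seed}.
#' @export
estimateRejectionRate <- function(scn, method = c("netdifm_asymptotic",
                                                  "netdifm_permutation",
                                                  "vewdm_permutation"),
                                  alpha = 0.05, nReplicates = 1000L,
                                  nPermutations = 1000L, seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  plan <- PermutationPlan(nPermutations)
  ps <- numeric(nReplicates)
  stats <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    d <- simulateCaseControl(scn)
    res <- switch(method,
      netdifm_asymptotic = netDifMTest(d, scn@net),
      netdifm_permutation = permutationTest(d, scn@net, "netdifm", plan),
      vewdm_permutation = permutationTest(d, scn@net, "vewdm", plan))
    ps[r] <- pValue(res)
    stats[r] <- testStatistic(res)
  }
  rate <- mean(ps < alpha)
  list(rate = rate, se = sqrt(rate * (1 - rate) / nReplicates),
       pValues = ps, statistics = stats, nReplicates = nReplicates,
       method = method, alpha = alpha, seed = seed)
}

#' Benchmark network fixtures
#'
#' The two seeded benchmark topologies shipped with the package as plain
#' edge-list files: a small network with 10 vertices and 21 edges and a
#' larger one with 20 vertices and 45 edges.  Both were generated with
#' [randomConnectedNetwork()] (seeds 104 and 201) subject to the scenario
#' requirement that the baseline covariance \eqn{I + 0.3 A} and the
#' shifted case covariances be positive definite.
#'
#' @return a [NetworkSpec-class].
#' @export
smallFixtureNetwork <- function() {
  loadEdgeList(system.file("extdata", "network_10v_21e.tsv",
                           package = "netdifm"),
               vertexUniverse = paste0("v", 1:10))
}

#' @rdname smallFixtureNetwork
#' @export
largeFixtureNetwork <- function() {
  loadEdgeList(system.file("extdata", "network_20v_45e.tsv",
                           package = "netdifm"),
               vertexUniverse = paste0("v", 1:20))
}
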