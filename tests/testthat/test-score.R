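test_that("vertex scores match the defining sum", {
  # forced arithmetic: Ybar = 0.5, so D = 0.5 + 0.5 + 0 + 0 = 1
  X <- cbind(a = c(1, 1, 0, 0), b = c(7, 7, 7, 7))
  d <- LabeledDataset(X, c(1, 1, 0, 0))
  ds <- vertexScores(d)
  expect_equal(unname(ds["a"]), 1)
  expect_equal(unname(ds["b"]), 0)  # constant column: centering identity

  toy <- makeToyData(30, 4, seed = 11)
  expect_equal(unname(vertexScores(toy)),
               oracleVertexScores(dataMatrix(toy), groupLabels(toy)))
})

test_that("edge scores match the literal loop oracle", {
  net <- squareNet()
  # constant endpoint column: centered factor vanishes
  X <- cbind(g1 = rnorm(10), g2 = rep(3, 10), g3 = rnorm(10),
             g4 = rnorm(10))
  d <- LabeledDataset(X, rep(c(1L, 0L), 5))
  expect_equal(unname(edgeScores(d, net)["g1--g2"]), 0)

  # two-sample toy, verified by hand: Ybar = 0.5, pooled means 0, so
  # D^E = 0.5*(1)(1) + (-0.5)(-1)(-1) = 0
  d2 <- LabeledDataset(cbind(g1 = c(1, -1), g2 = c(1, -1)), c(1, 0))
  net2 <- NetworkSpec(c("g1", "g2"), rbind(c(1L, 2L)))
  expect_equal(unname(edgeScores(d2, net2)), 0)

  toy <- makeToyData(30, 4, seed = 12)
  expect_equal(unname(edgeScores(toy, net)),
               oracleEdgeScores(dataMatrix(toy), groupLabels(toy),
                                edgeMatrix(net)))
})

test_that("score covariance equals per-entry formula evaluation", {
  toy <- makeToyData(30, 4, seed = 13)
  net <- squareNet()
  dec <- scoreCovariance(toy, net)
  S <- covarianceMatrix(dec)
  oracle <- oracleSigma(dataMatrix(toy), groupLabels(toy), edgeMatrix(net))
  expect_equal(S, oracle, tolerance = 1e-12)
  expect_equal(S, t(S))
  expect_gte(min(eigen(S, TRUE, TRUE)$values),
             -1e-10 * max(eigen(S, TRUE, TRUE)$values))
  expect_equal(dec@labelWeightSum,
               sum((groupLabels(toy) - mean(groupLabels(toy)))^2))

  # single-block case M=1, K=0
  net1 <- NetworkSpec("g1", matrix(integer(0), ncol = 2))
  d1 <- LabeledDataset(dataMatrix(toy)[, 1, drop = FALSE],
                       groupLabels(toy))
  dec1 <- scoreCovariance(d1, net1)
  expect_equal(covarianceMatrix(dec1)[1, 1],
               dec1@labelWeightSum * var(dataMatrix(toy)[, 1]))
})

test_that("the quadratic form matches an explicit-inverse oracle", {
  toy <- makeToyData(30, 4, seed = 14)
  net <- squareNet()
  dec <- scoreCovariance(toy, net)
  D <- unname(scoreVector(dec))
  expect_equal(netDifMStatistic(dec),
               oracleQuadForm(covarianceMatrix(dec), D),
               tolerance = 1e-10)

  # D = 0 and identity-metric closed forms
  mk <- function(D, S) new("ScoreDecomposition", Dvertex = D,
                           Dedge = numeric(0), Sigma = S,
                           labelWeightSum = 1,
                           vertexNames = paste0("v", seq_along(D)),
                           edgeNames = character(0))
  expect_equal(netDifMStatistic(mk(rep(0, 3), diag(3))), 0)
  expect_equal(netDifMStatistic(mk(c(1, 2, 3), diag(3))), 14)
})

test_that("singular covariance errors with the pruning remedy named", {
  set.seed(15)
  x <- rnorm(30)
  X <- cbind(g1 = x, g2 = x, g3 = rnorm(30))  # duplicated column
  d <- LabeledDataset(X, rep(c(1L, 0L), 15))
  net <- triangleNet()
  expect_error(netDifMTest(d, net), "pruneEdges")
  dec <- scoreCovariance(d, net)
  expect_true(is.finite(netDifMStatistic(dec, solver = "pseudoinverse")))
  expect_true(is.finite(netDifMStatistic(dec, solver = "ridge",
                                         ridgeLambda = 1e-6)))
  expect_error(netDifMStatistic(dec, solver = "ridge"), "ridgeLambda")
})

test_that("asymptotic p-values follow the chi-square survival function", {
  toy <- makeToyData(40, 3, seed = 16)
  net <- triangleNet()
  res <- netDifMTest(toy, net)
  expect_equal(degreesOfFreedom(res), 6L)  # M + K
  expect_equal(pValue(res),
               pchisq(testStatistic(res), 6, lower.tail = FALSE))
  # statistic 0 -> p = 1; statistic = df -> quadrature of the density
  expect_equal(pchisq(0, 6, lower.tail = FALSE), 1)
  quad <- integrate(function(x) dchisq(x, 6), lower = 6, upper = Inf,
                    rel.tol = 1e-10)$value
  expect_equal(pchisq(6, 6, lower.tail = FALSE), quad, tolerance = 1e-8)
})

test_that("statistic is invariant to label swap, edge order and scaling", {
  toy <- makeToyData(30, 4, seed = 17)
  net <- squareNet()
  dec <- scoreCovariance(toy, net)
  stat <- netDifMStatistic(dec)

  # label-swap antisymmetry: D negates, statistic and Sigma unchanged
  swapped <- LabeledDataset(dataMatrix(toy), 1L - groupLabels(toy))
  dec2 <- scoreCovariance(swapped, net)
  expect_equal(scoreVector(dec2), -scoreVector(dec))
  expect_equal(covarianceMatrix(dec2), covarianceMatrix(dec))
  expect_equal(netDifMStatistic(dec2), stat)

  # Sigma is invariant under any label permutation (factorization)
  set.seed(18)
  for (i in 1:3) {
    perm <- LabeledDataset(dataMatrix(toy), sample(groupLabels(toy)))
    expect_equal(covarianceMatrix(scoreCovariance(perm, net)),
                 covarianceMatrix(dec))
  }

  # permuting the edge positions of (D, Sigma) leaves the form unchanged
  D <- unname(scoreVector(dec)); S <- covarianceMatrix(dec)
  ord <- c(1:4, 4 + c(3, 1, 4, 2))
  expect_equal(oracleQuadForm(S[ord, ord], D[ord]), stat,
               tolerance = 1e-10)

  # rescaling a column rescales its scores but not the statistic
  X <- dataMatrix(toy); X[, 2] <- 5 * X[, 2]
  dec3 <- scoreCovariance(LabeledDataset(X, groupLabels(toy)), net)
  expect_equal(dec3@Dvertex[2], 5 * dec@Dvertex[2])
  expect_equal(netDifMStatistic(dec3), stat, tolerance = 1e-9)
})

test_that("errors on degenerate inputs propagate", {
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("g1", "g2")))
  net <- NetworkSpec(c("g1", "g3"), rbind(c(1L, 2L)))
  d <- LabeledDataset(X, c(1L, 0L, 1L, 0L))
  expect_error(edgeScores(d, net), "do not cover")
  d2 <- LabeledDataset(X[1:2, ], c(1L, 0L))
  net2 <- NetworkSpec(c("g1", "g2"), rbind(c(1L, 2L)))
  expect_error(scoreCovariance(d2, net2), "N >= 3")
})

test_that("per-vertex subnetwork test keeps df and score bookkeeping", {
  net <- smallFixtureNetwork()
  scn <- makeScenario(net, "null", n = 120)
  set.seed(19)
  d <- simulateCaseControl(scn)
  for (v in c("v1", "v5")) {
    res <- vertexSubnetworkTest(d, net, v)
    deg <- vertexDegree(net, v)
    expect_equal(degreesOfFreedom(res), 1L + deg)  # focal vertex + edges

    # consistency oracle: restrict the star's scores by hand
    sub <- incidentSubnetwork(net, v)
    dsub <- LabeledDataset(dataMatrix(d)[, vertexNames(sub)],
                           groupLabels(d))
    dec <- scoreCovariance(dsub, sub)
    sel <- c(match(v, vertexNames(sub)),
             vertexCount(sub) + seq_len(edgeCount(sub)))
    D <- unname(scoreVector(dec))[sel]
    S <- covarianceMatrix(dec)[sel, sel]
    expect_equal(testStatistic(res), oracleQuadForm(S, D),
                 tolerance = 1e-10)
    # restricted statistic differs from the whole-network statistic
    expect_false(isTRUE(all.equal(testStatistic(res),
                                  testStatistic(netDifMTest(d, net)))))
  }

  # permutation flavors run on the same restricted score set
  resP <- vertexSubnetworkTest(d, net, "v5", method = "permutation",
                               nPermutations = 99, seed = 20)
  expect_equal(methodLabel(resP), "netdifm_permutation")
  expect_true(pValue(resP) %in% ((0:99) / 99))
  resV <- vertexSubnetworkTest(d, net, "v5", method = "vewdm",
                               nPermutations = 99, seed = 20)
  expect_equal(methodLabel(resV), "vewdm_permutation")
  # observed restricted statistic: T_focal^2 + mean U^2 over incident edges
  i5 <- match("v5", vertexNames(net))
  inc <- edgeMatrix(net)[edgeMatrix(net)[, 1] == i5 |
                           edgeMatrix(net)[, 2] == i5, , drop = FALSE]
  Us <- apply(inc, 1, function(e) edgeU(d, vertexNames(net)[e]))
  expect_equal(testStatistic(resV), vertexT(d, "v5")^2 + mean(Us^2),
               tolerance = 1e-10)

  iso <- NetworkSpec(c("v1", "v2", "v3"), rbind(c(1L, 2L)))
  di <- LabeledDataset(matrix(rnorm(30), 10, 3,
                              dimnames = list(NULL, c("v1", "v2", "v3"))),
                       rep(c(1L, 0L), 5))
  expect_error(vertexSubnetworkTest(di, iso, "v3"), "degree 0")
})

test_that("a shifted vertex attains the smallest subnetwork p-value", {
  net <- smallFixtureNetwork()
  scn <- makeScenario(net, "vertex", n = 200,
                      vertexShifts = c(v4 = 0.6))
  set.seed(21)
  wins <- replicate(15, {
    d <- simulateCaseControl(scn)
    ps <- vapply(vertexNames(net), function(v)
      pValue(vertexSubnetworkTest(d, net, v)), numeric(1))
    names(which.min(ps)) == "v4"
  })
  expect_gt(mean(wins), 0.5)  # majority vote across replicates
})
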