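test_that("buildSigma places edge correlations and verifies definiteness", {
  net0 <- NetworkSpec(c("a", "b"), matrix(integer(0), ncol = 2))
  expect_equal(unname(buildSigma(net0, numeric(0))), diag(2))

  net1 <- NetworkSpec(c("a", "b"), rbind(c(1L, 2L)))
  s <- buildSigma(net1, 0.3)
  expect_equal(unname(s), matrix(c(1, 0.3, 0.3, 1), 2))
  expect_equal(sort(eigen(s, TRUE, TRUE)$values), c(0.7, 1.3))

  # eigen-decomposition oracle on the benchmark fixture
  net <- smallFixtureNetwork()
  sig <- buildSigma(net, 0.3)
  expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  A <- matrix(0, 10, 10)
  A[edgeMatrix(net)] <- 1; A <- A + t(A)
  expect_equal(unname(sig), diag(10) + 0.3 * A)

  # a 0.8-correlation path is not positive definite: no silent repair
  path <- NetworkSpec(c("a", "b", "c"), rbind(c(1L, 2L), c(2L, 3L)))
  expect_error(buildSigma(path, 0.8), "min eigenvalue")
  expect_error(buildSigma(net1, c(0.3, 0.3)), "one beta per edge")
})

test_that("random connected networks have the requested size and topology", {
  for (par in list(c(10, 21), c(20, 45), c(40, 54))) {
    net <- randomConnectedNetwork(par[1], par[2], seed = 5)
    expect_equal(vertexCount(net), par[1])
    expect_equal(edgeCount(net), par[2])
    g <- igraph::graph_from_edgelist(edgeMatrix(net), directed = FALSE)
    expect_true(igraph::is_connected(g))
  }
  # K = M - 1 gives a tree: connected and acyclic
  tree <- randomConnectedNetwork(12, 11, seed = 6)
  g <- igraph::graph_from_edgelist(edgeMatrix(tree), directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::girth(g)$girth, Inf)

  expect_identical(randomConnectedNetwork(10, 21, 7),
                   randomConnectedNetwork(10, 21, 7))
  expect_error(randomConnectedNetwork(10, 8, 1), "K must lie")
  expect_error(randomConnectedNetwork(10, 46, 1), "K must lie")
  # the seeded generator leaves the caller's RNG stream untouched
  set.seed(8); before <- rnorm(1)
  set.seed(8); invisible(randomConnectedNetwork(10, 21, 9))
  expect_equal(rnorm(1), before)
})

test_that("group draws have the requested moments and transforms", {
  net1 <- NetworkSpec(c("a", "b"), rbind(c(1L, 2L)))
  sig <- buildSigma(net1, 0.3)
  set.seed(51)
  X <- simulateGroup(c(0, 0), sig, 1e5)
  expect_lt(max(abs(colMeans(X))), 3 / sqrt(1e5) * 1.1)
  # Fisher-z confidence interval for the sample correlation
  zhat <- atanh(cor(X[, 1], X[, 2]))
  expect_lt(abs(zhat - atanh(0.3)), 3 / sqrt(1e5 - 3))

  Xe <- simulateGroup(c(0, 0), sig, 500, transform = "exp_all")
  expect_true(all(Xe > 0))
  Xs <- simulateGroup(c(0, 0), sig, 500, transform = "exp_subset",
                      transformVertices = 2L)
  expect_true(all(Xs[, 2] > 0) && any(Xs[, 1] < 0))
})

test_that("case/control simulation realizes the configured shifts", {
  net <- smallFixtureNetwork()
  h0 <- makeScenario(net, "null", n = 100)
  expect_true(isNullScenario(h0))
  set.seed(52)
  d <- simulateCaseControl(h0)
  expect_equal(unname(groupSizes(d)), c(50L, 50L))
  expect_equal(colnames(dataMatrix(d)), vertexNames(net))

  # mean-shift scenario: group mean difference ~ 0.2 at shifted vertices
  s1 <- makeScenario(net, "vertex", n = 40000, vertexShifts = c(0.2, 0.2))
  expect_false(isNullScenario(s1))
  shifted <- which(s1@muCase != s1@muControl)
  expect_length(shifted, 2L)
  set.seed(53)
  d1 <- simulateCaseControl(s1)
  X <- dataMatrix(d1); y <- groupLabels(d1)
  diffs <- colMeans(X[y == 1, shifted]) - colMeans(X[y == 0, shifted])
  expect_lt(max(abs(diffs - 0.2)), 3 * sqrt(2 / 20000))

  # edge-shift scenario: per-group correlations move by the beta shifts
  s2 <- makeScenario(net, "edge", n = 40000,
                     edgeShifts = c(-0.2, 0.2, 0.2))
  moved <- which(s2@betaCase != s2@betaControl)
  expect_length(moved, 3L)
  set.seed(54)
  d2 <- simulateCaseControl(s2)
  X2 <- dataMatrix(d2); y2 <- groupLabels(d2)
  for (k in moved) {
    e <- edgeMatrix(net)[k, ]
    rD <- cor(X2[y2 == 1, e[1]], X2[y2 == 1, e[2]])
    rC <- cor(X2[y2 == 0, e[1]], X2[y2 == 0, e[2]])
    expect_lt(abs((rD - rC) - (s2@betaCase[k] - s2@betaControl[k])), 0.05)
  }

  # requesting a non-positive-definite group covariance fails loudly
  path <- NetworkSpec(c("a", "b", "c"), rbind(c(1L, 2L), c(2L, 3L)))
  expect_error(SimulationScenario(path, 0, 0, betaCase = 0.8,
                                  betaControl = 0.3, nCase = 10,
                                  nControl = 10),
               "positive definite")
})

test_that("rejection-rate estimation returns diagnostics and edge cases", {
  net <- triangleNet()
  scn <- makeScenario(net, "null", n = 50)
  est <- estimateRejectionRate(scn, "netdifm_asymptotic", alpha = 1,
                               nReplicates = 20, seed = 55)
  expect_equal(est$rate, 1)  # vacuous threshold
  expect_length(est$pValues, 20)
  expect_equal(est$se, 0)
  est2 <- estimateRejectionRate(scn, "netdifm_asymptotic", alpha = 0.05,
                                nReplicates = 50, seed = 56)
  expect_equal(est2$rate, mean(est2$pValues < 0.05))
  expect_equal(est2$se, sqrt(est2$rate * (1 - est2$rate) / 50))
})
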