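# Independent brute-force oracles: every formula is evaluated by literal
# loops over samples, never through the package's vectorized code paths.

oracleVertexScores <- function(X, y) {
  ybar <- mean(y)
  d <- numeric(ncol(X))
  for (i in seq_len(ncol(X)))
    for (l in seq_len(nrow(X)))
      d[i] <- d[i] + (y[l] - ybar) * X[l, i]
  d
}

oracleEdgeScores <- function(X, y, edges) {
  ybar <- mean(y)
  xbar <- colMeans(X)
  d <- numeric(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    for (l in seq_len(nrow(X)))
      d[k] <- d[k] + (y[l] - ybar) * (X[l, i] - xbar[i]) * (X[l, j] - xbar[j])
  }
  d
}

# Literal sample covariance of two vectors (N-1 denominator).
oracleCov2 <- function(a, b) {
  s <- 0
  for (l in seq_along(a)) s <- s + (a[l] - mean(a)) * (b[l] - mean(b))
  s / (length(a) - 1)
}

# Entry-by-entry evaluation of the score covariance blocks.
oracleSigma <- function(X, y, edges) {
  ybar <- mean(y)
  lws <- sum((y - ybar)^2)
  xbar <- colMeans(X)
  m <- ncol(X); k <- nrow(edges)
  W <- matrix(0, nrow(X), m + k)
  W[, seq_len(m)] <- X
  for (e in seq_len(k))
    W[, m + e] <- (X[, edges[e, 1L]] - xbar[edges[e, 1L]]) *
      (X[, edges[e, 2L]] - xbar[edges[e, 2L]])
  S <- matrix(0, m + k, m + k)
  for (p in seq_len(m + k))
    for (q in seq_len(m + k))
      S[p, q] <- lws * oracleCov2(W[, p], W[, q])
  S
}

oracleQuadForm <- function(Sigma, D) drop(t(D) %*% solve(Sigma) %*% D)

# Per-element recomputation of the element-wise measure from raw group
# vectors, literal formulas throughout.
oracleVewdm <- function(X, y, edges) {
  XD <- X[y == 1, , drop = FALSE]
  XC <- X[y == 0, , drop = FALSE]
  nD <- nrow(XD); nC <- nrow(XC)
  Tsq <- vapply(seq_len(ncol(X)), function(i) {
    num <- mean(XD[, i]) - mean(XC[, i])
    den <- sqrt(oracleCov2(XD[, i], XD[, i]) / nD +
                  oracleCov2(XC[, i], XC[, i]) / nC)
    (num / den)^2
  }, numeric(1))
  z <- function(r) 0.5 * log((1 + r) / (1 - r))
  Usq <- vapply(seq_len(nrow(edges)), function(k) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    rD <- oracleCov2(XD[, i], XD[, j]) /
      sqrt(oracleCov2(XD[, i], XD[, i]) * oracleCov2(XD[, j], XD[, j]))
    rC <- oracleCov2(XC[, i], XC[, j]) /
      sqrt(oracleCov2(XC[, i], XC[, i]) * oracleCov2(XC[, j], XC[, j]))
    ((z(rD) - z(rC)) / sqrt(1 / (nD - 3) + 1 / (nC - 3)))^2
  }, numeric(1))
  mean(Tsq) + mean(Usq)
}

# Small random dataset with balanced labels and mildly correlated columns.
makeToyData <- function(n = 30, m = 4, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n * m), n, m)
  X <- base + 0.4 * rowMeans(base)
  colnames(X) <- paste0("g", seq_len(m))
  y <- rep(c(1L, 0L), length.out = n)
  LabeledDataset(X, y)
}

triangleNet <- function() {
  NetworkSpec(c("g1", "g2", "g3"),
              rbind(c("g1", "g2"), c("g2", "g3"), c("g1", "g3")))
}

# 4 vertices, 4 edges: a square with one diagonal plus pendant structure.
squareNet <- function() {
  NetworkSpec(paste0("g", 1:4),
              rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(1L, 4L)))
}

# A length-n vector pair with exact sample correlation r: built by
# Gram-Schmidt from random draws, so cor(u, w) == r to machine precision.
exactCorrPair <- function(n, r, seed) {
  set.seed(seed)
  u <- scale(rnorm(n))[, 1]
  v <- rnorm(n)
  v <- scale(v - u * sum(u * v) / sum(u^2))[, 1]
  w <- r * u + sqrt(1 - r^2) * v
  cbind(u = u, w = w)
}
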