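---
title: "Testing group differences in weighted biological networks"
author: "netdifm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing group differences in weighted biological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdifm)
```

## The problem

A weighted biological network is an undirected graph whose M vertices are
biomolecules (genes, proteins, metabolites) measured on each sample and
whose K edges carry a continuous association strength — here the Pearson
correlation — between the two endpoint variables.  Two study groups (say
cases and controls) can differ in such a network in two distinct ways:
the *levels* of the vertices can shift, and the *connection strengths* of
the edges can change.  Methods that compare only the topology, or only
differential correlation, lose power when both kinds of change are
present and individually weak.  `netdifm` tests the global null
hypothesis that the two groups share the same network — identical vertex
levels *and* identical edge strengths — with a single statistic that
aggregates both.

The topology itself is taken as fixed and known (from a pathway database,
an interaction network, or prior biology).  Learning the network
structure from data is out of scope.

## The quadratic-form score statistic

Let $Y_l \in \{0, 1\}$ be the group label of sample $l$
($l = 1, \dots, N$) and $x_{li}$ the value of vertex $i$.  Two score
vectors measure the association of each network element with the label:

* vertex scores
  $D^V_i = \sum_{l=1}^N (Y_l - \bar Y)\, x_{li}$, one per vertex — the
  score statistic for a shift in vertex $i$'s mean level;
* edge scores
  $D^E_k = \sum_{l=1}^N (Y_l - \bar Y) (x_{li} - \bar x_i)(x_{lj} - \bar x_j)$
  for edge $k = (i, j)$ — the score statistic for a change in the
  covariance of the two endpoints, with $\bar x_i$ the pooled mean over
  all $N$ samples.

Writing $D = (D^V, D^E)$ and $\Sigma = \widehat{\mathrm{cov}}(D)$, the
network difference measure is the quadratic form

$$\mathrm{NetDifM} = D^\top \Sigma^{-1} D ,$$

which for large samples is centrally $\chi^2$ distributed with $M + K$
degrees of freedom under the null.  The covariance estimate is assembled
from three blocks ($\Sigma_V$, $\Sigma_E$, and the cross block
$\Sigma_{VE}$), each of the form
$\sigma_{pq} = \sum_l (Y_l - \bar Y)^2\, \mathrm{cov}(W_p, W_q)$ where
the working variables $W$ are the data columns $X$ and the centered
cross-products $Z_k = (X_i - \bar X_i)(X_j - \bar X_j)$.  Because the
covariance factor does not involve $l$, the whole matrix factorizes as

$$\Sigma = \Big(\textstyle\sum_l (Y_l - \bar Y)^2\Big) \times
  \mathrm{cov}\big([X \mid Z]\big).$$

Two consequences are used throughout the package and asserted by the
test suite: $\Sigma$ is invariant under any permutation of the labels
(the first factor depends only on the group sizes), and recoding
$Y \mapsto 1 - Y$ negates $D$ but leaves the statistic unchanged.

### Numerical choices

* **Covariance denominator.** The sample covariance uses the unbiased
  $N - 1$ denominator (`stats::cov`).  The choice is asymptotically
  immaterial (it rescales the statistic by $N/(N-1)$); the chi-square
  calibration test in the suite is the arbiter that it is adequate at
  finite $N$.
* **Solving, not inverting.** The quadratic form is computed by a linear
  solve (Cholesky in the permutation engine), never by forming
  $\Sigma^{-1}$.  A reciprocal-condition-number guard at $10^{-12}$
  refuses numerically singular covariances with an error that names the
  remedy: prune weakly correlated edges first (`pruneEdges()`, using the
  pooled, label-blind correlation so the null topology is not chosen
  with group information), or opt into the Moore–Penrose or ridge
  fallback solvers.
* **Edge ordering.** Edges are normalized to index pairs $(i, j)$ with
  $i < j$ and sorted lexicographically, fixing positions
  $M+1, \dots, M+K$ of the score vector.  The statistic itself is
  invariant to this ordering (a coordinate permutation of a quadratic
  form), which the suite asserts; the canonical order exists so that
  results are bit-reproducible.
* **Label coding.** Labels must be exactly 0/1.  Any other coding is an
  error, never silently recoded, because the vertex scores are not
  invariant to affine relabeling.

## The element-wise comparator

As a baseline, the element-wise measure sums standardized per-element
differences:

$$\mathrm{VEWDM} = \frac1M \sum_{i=1}^M T_i^2 +
  \frac1K \sum_{(i,j) \in E} U_{ij}^2,$$

with $T_i$ the Welch-standardized difference of group means of vertex
$i$, and $U_{ij} = (z_{ij}^D - z_{ij}^C) / \sqrt{1/(n_D - 3) + 1/(n_C - 3)}$
the Fisher r-to-z differential correlation of edge $(i, j)$.  Each
unordered edge is counted once: the double-sum notation over ordered
pairs, normalized by $K$, is ambiguous by a factor of two, and the
once-per-edge convention is fixed here so printed statistic values are
well defined (permutation inference is unaffected by the constant).
Because the joint null distribution of the $T_i$ and $U_{ij}$ depends on
the network structure, no asymptotic p-value is offered; inference is by
permutation only.

## Permutation inference

The permutation engine implements the standard label-shuffling null:
compute the observed statistic, reassign subjects to groups uniformly at
random with group sizes fixed, recompute $Q$ times, and report
$p = \frac1Q \sum_i I(\mathrm{stat}^*_i > \mathrm{stat})$ with a strict
inequality (ties count as non-exceedances; an optional
$(1 + \mathrm{count})/(1 + Q)$ correction is available behind a flag,
default off, so the plain estimator remains the reference convention).
For small balanced designs the engine can enumerate all
$\binom{N}{n_{\mathrm{case}}}$ assignments exactly.

The label-invariance of $\Sigma$ makes the quadratic-form permutation
test cheap: $\Sigma$ and its Cholesky factor are computed once, and each
permutation costs one matrix–vector product and one triangular solve.
All $Q$ permutations are evaluated as a single matrix product, so a
1000-permutation test on a 10-vertex/21-edge network at $N = 100$ runs
in milliseconds.  The element-wise statistic is vectorized the same way:
group means, variances, and per-edge correlations for all permutations
are linear images of three cross-products with the label-indicator
matrix.  The batch engines are asserted equal to the scalar
(per-element, literal-formula) implementations in the test suite.

## Per-vertex localization

Beyond the whole-network test, a single vertex can be tested by treating
the vertex together with its connected edges as a small network: the
score vector is restricted to the focal vertex's score and the scores of
its incident edges (df $= 1 + d$ for a degree-$d$ vertex).  The
restriction deliberately excludes the neighbors' own vertex scores: if a
neighbor's level carries signal, including it would spread one vertex's
effect over all adjacent subnetwork tests, defeating localization.  The
suite verifies on simulated data that when exactly one vertex's mean is
shifted, that vertex attains the smallest subnetwork p-value in the
majority of replicates.  An isolated (degree-0) vertex has no incident
edges and is reported as untestable rather than silently tested on its
mean alone.

## The simulation module

The generator draws each group from a multivariate normal
$N_M(\mu, \Sigma)$ whose covariance has unit diagonal, the per-edge
correlation $\beta_{ij}$ at edge positions, and zero elsewhere, so the
network topology *is* the dependence structure.  Matrices are checked
for positive definiteness (minimum eigenvalue $> 10^{-10}$) and never
silently repaired.

Design choices, fixed once:

* **Benchmark topologies.** Two seeded random connected graphs at the
  benchmark scales, 10 vertices/21 edges and 20 vertices/45 edges,
  shipped as plain edge-list files (`inst/extdata/`) and reproduced
  bit-for-bit by `randomConnectedNetwork()` with seeds 104 and 201.
  The generator builds a random spanning tree and adds distinct extra
  edges, so any connected scale in the valid range can be instantiated
  (e.g. a 40-vertex/54-edge network for scalability studies).  The
  seeds were chosen when the fixtures were created, subject to the
  validity constraint that the baseline and shifted covariances below
  are comfortably positive definite.
* **Baseline correlation** $\beta = 0.3$ on every edge.  Type I error
  calibration is insensitive to this choice; absolute power levels are
  not, so power results are meaningful as orderings and trends rather
  than as universal constants.
* **Group sizes.** A quoted sample size $n$ means total $N$ split
  equally ($n/2$ per group), the simulation-literature default; the
  element-wise test's $n - 3$ denominators are then well defined at all
  benchmark sizes.
* **Alternatives.** Scenario 1 shifts two vertex means by $+0.2$;
  scenario 2 shifts three edge correlations by $-0.2, +0.2, +0.2$;
  scenario 3 applies both.  The shifted positions are drawn once by a
  fixed selection seed (the benchmark topologies are themselves
  synthetic, so no canonical "vertex 3" exists), subject to both group
  covariances remaining positive definite.
* **Non-normal robustness.** An elementwise exponential transform
  applied to a fixed-seed half of the vertices (or to all of them)
  after the MVN draw produces skewed, log-normal-like marginals in both
  groups, preserving the null when the groups' parameters are equal.

What the generator emulates is the *dependence-and-shift* structure of
two-group omics data on a known pathway; what it does not emulate are
heavy-tailed measurement error beyond the exponential transform,
missingness (the data classes reject missing values; imputation is
upstream), confounding covariates (the score is a pure two-group
comparison), and unknown topology.  Passing calibration and power tests
on these inputs therefore demonstrates correctness of the statistics and
their inference machinery, not robustness to every failure mode of real
expression or genotype data.

### Study sizes used in the shipped experiments

The packaged acceptance experiments (`scripts/acceptance.R` and the
calibration tests) use 1000 replicates for type I error with 1000
permutations per replicate, 1000 replicates for the chi-square
calibration at $N = 800$, and 500 replicates with 500 permutations for
the scenario-3 power comparison at $N \in \{100, 300, 500\}$ — the
replicate counts at which a rate has Monte Carlo standard error
$\approx 0.007$ ($\approx 0.022$ for power), matching the precision the
benchmark comparisons need.  At 1000 replicates a type-I-error
band of $\pm 0.015$ around a reference value is about two binomial
standard errors wide, so individual cells near a band edge can cross it
by simulation noise alone; the calibration conclusions rest on the
ensemble of cells, not on any single one.

## Preprocessing to vertex level

Real networks are defined over genes while measurements arrive at a
finer granularity (probe sets, SNPs).  Two collapses are provided:
per-vertex averaging of mapped features, and the first principal
component of each feature block.  PCA is computed on standardized
features (correlation matrix) over the pooled sample, ignoring labels so
no group information leaks into vertex construction, and the PC1 sign is
fixed by making the largest-magnitude loading positive — the vertex
scores are not sign-invariant, so a deterministic orientation is
required.  SNP blocks are assumed to be numerically coded upstream
(e.g. additive dosage); genotype quality control is out of scope.

## Known limitations

* Binary traits only; no covariate adjustment, no more than two groups.
* The statistic requires an invertible score covariance; for dense
  networks relative to $N$, prune weak edges first or use the fallback
  solvers, both of which change the testable hypothesis slightly (the
  pruned network, or a regularized metric).
* Asymptotic inference is conservative at small $N$ (the permutation
  test is the recommended default below a few hundred samples per
  group); its finite-sample rejection rate at large $N$ approaches the
  nominal level at a speed that depends on the topology and the
  baseline correlations.
* Edge strength is Pearson correlation; regression-slope or partial
  correlation edge weights are not implemented.
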