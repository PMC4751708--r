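Package: netdifm
Title: Score-Based Tests for Group Differences in Weighted Biological
    Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical comparison of a weighted biological network
    (vertex levels plus edge connection strengths) between two groups of
    samples, such as cases and controls.  Implements the score-based
    network difference measure NetDifM, a quadratic form over per-vertex
    and per-edge score statistics with an asymptotic chi-square null
    distribution, and the element-wise comparator VEWDM built from
    standardized mean differences and Fisher r-to-z differential
    correlations.  Inference is available through the asymptotic
    distribution or a label-permutation engine.  Includes a simulation
    module generating multivariate normal case/control data with
    network-structured covariance for type I error and power studies, and
    preprocessing helpers that collapse multi-feature biomolecules (probe
    sets, SNP blocks) to one value per network vertex by averaging or by
    first principal component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, StatisticalMethod, GeneExpression
RoxygenNote: 7.3.3
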