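Package: discern
Title: Differential Regulator-Network Perturbation Scores for
    Two-Condition Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genes whose sparse regulator network differs
    between two biological conditions (e.g. tumor and normal tissue).
    Fits an L1-penalized linear model of each gene's expression on a set
    of candidate regulators in each condition and scores genes by how
    poorly the weights learned in one condition explain the data in the
    other (the DISCERN likelihood-ratio score), together with the
    comparison scores D0, local network similarity (LNS), Glass d-score
    and one-way ANOVA. Includes a conservative pooled label-permutation
    null with empirical p-values and Benjamini-Hochberg FDR, per-gene
    permutation p-value variants, a multivariate-normal synthetic
    benchmark with perturbed/shared/isolated variable categories and ROC
    comparison, hypergeometric gene-set enrichment, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
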