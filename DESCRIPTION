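Package: episubnet
Title: Epigenetic Subnetwork Inference by Bayesian Regression on
    Differential Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects epigenetic subnetworks in matched DNA methylation and
    gene expression data. Differential co-expression and co-methylation
    networks are built on a protein-interaction scaffold using the Fisher
    z-statistic on condition-specific correlations; gene modules are
    detected by symmetric nonnegative matrix factorization with rank
    selection via permutation-tested module density; each module is
    summarized by its eigengene (first right-singular vector); and, for
    every expression response module, the subset of methylation predictor
    modules that best explains it is selected by Bayesian linear
    regression with a biologically informed Zellner g-prior and
    expected-BIC subset selection. Includes prognostic-index survival
    analysis of the detected modules and a seeded simulation engine
    (inverse-Wishart correlated modules, planted predictor-response
    wiring, random bipartite prior networks) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
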