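Package: treefar
Title: Tree-Aggregated Factor Regression for Microbiome-Metabolome Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sparse, low-rank multivariate regression relating compositional
    microbiome profiles to multivariate continuous outcomes such as metabolite
    concentrations. Aggregates rare taxa along the taxonomic tree by expanding
    the design with ancestor-node features, enforces the compositional zero-sum
    identifiability constraint on the coefficient matrix, and extracts sparse
    unit-rank components sequentially with an adaptive elastic-net penalty and
    response deflation. Includes a dense linear-constrained reduced-rank
    regression baseline, a zero-inflated lognormal synthetic-data engine for
    benchmarking, support-recovery and estimation-error metrics, and post-fit
    interpretation utilities (latent factor scores, selected loadings, and
    phenotype association).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
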