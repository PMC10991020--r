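Package: spcawl
Title: Sparse Principal Component Analysis with Sparse Weights or Sparse
    Loadings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Alternating least-squares estimators for sparse principal
    component analysis with exact per-component cardinality control,
    placing sparsity either on the component weights (elastic-net update
    solved by a cardinality-truncated LARS-EN path) or on the loadings
    (hard-thresholded least squares with orthonormal scores).  Includes
    SVD-based and multistart initialization with best-of-starts selection,
    synthetic data generators for spiked-covariance, sparse-loadings and
    sparse-weights models with an exactly controlled proportion of error
    variance, component-recovery evaluation (zero/non-zero recovery rate,
    Tucker congruence of component scores, variance accounted for), and a
    seeded simulation-grid runner that emits long-format records.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
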