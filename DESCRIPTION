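Package: perturbGRN
Title: Perturbation-Based Gene Regulatory Network Inference with
    Bootstrap FDR Control and Gold-Standard-Free Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers gene regulatory networks (GRNs) from known-design
    gene-knockdown expression data under a linear steady-state
    perturbation model. Provides three sparse estimators (least squares
    with cutoff, LASSO, and total least squares with cutoff), nested
    bootstrapping with false-discovery-rate control against shuffled-data
    null distributions, and a gold-standard-free assessment of any GRN's
    predictiveness via balanced-error leave-one-gene-out cross-validation
    compared to degree-preserving shuffled-topology and shuffled-data
    nulls. Includes a simulator of stable sparse networks and knockdown
    experiments so every stage can be exercised on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    pracma,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
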