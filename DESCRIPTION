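Package: bfiglm
Title: Bayesian Federated Inference for Generalized Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-shot Bayesian federated inference (BFI) for generalized
    linear models estimated across medical centers whose subject-level data
    cannot be pooled. Each center fits a ridge-penalized maximum a posteriori
    (MAP) model locally and shares only its parameter estimates, posterior
    curvature, prior precision and sample size; these summaries are combined
    centrally, in a single communication round, into an approximation of the
    estimate that an analysis of the pooled data would have produced.
    Supports homogeneous populations as well as heterogeneity through
    center-specific parameters (intercepts, slopes, error variances),
    cluster-specific intercepts, and continuous center-level covariates;
    includes credible intervals, Wald tests, leave-one-out heterogeneity
    diagnostics, weighted-average and single-center baseline estimators, a
    simulation harness with MSE bookkeeping, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
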