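Package: phylou
Title: Bayesian Linear Ornstein-Uhlenbeck Models for Phylogenetic
    Comparative Hypotheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits linear Ornstein-Uhlenbeck (OU) models of continuous trait
    evolution on a phylogeny in a Bayesian framework: multi-optima models with
    fixed selective regimes painted on the tree, direct-effect (allometric
    constraint) and adaptive (optimum-tracking) continuous-predictor models,
    and multilevel varying-intercept/varying-slope extensions with centered or
    non-centered parameterizations.  Includes Hansen regime-weight design
    matrices, phylogenetic half-life and stationary-variance
    reparameterizations, measurement error in response and predictors, Mk
    ancestral-state reconstruction for building regime paintings from tip
    states, a built-in No-U-Turn sampler with convergence diagnostics
    (split rank-normalized R-hat, effective sample size), model comparison by
    PSIS-LOO, WAIC and bridge-sampling Bayes factors, prior and posterior
    predictive checks, and a generative simulator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
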