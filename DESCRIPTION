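Package: twinace
Title: Classical Twin-Design ACE Modelling of Infant Adaptive Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, descriptive statistics, covariate screening and
    full-information maximum-likelihood (FIML) variance-component modelling
    for classical twin studies of paired phenotypes.  Implements Gaussian
    generalized estimating equations with cluster-robust (sandwich)
    standard errors for twin-clustered covariate screening and polygenic
    score association, saturated and constrained multivariate-normal twin
    models, univariate ACE and bivariate correlated-factors ACE models with
    likelihood-based profile confidence intervals, decomposition of a
    phenotypic correlation into additive genetic, shared environmental and
    unique environmental contributions, and simulation-based post-hoc power
    analysis.  A synthetic twin-pair generator reproduces the covariance
    structure the models assume so that every stage is testable without
    restricted participant-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
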