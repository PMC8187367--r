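Package: mebnet
Title: Mixed-Effect Bayesian Networks for Personal Effects on Longitudinal Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits mixed-effect Bayesian networks: bipartite directed graphical
    models in which each biomarker response is regressed on a shared set of
    standardized predictors with population-level (general) coefficients and
    correlated subject-level (personal) random slopes, AR(1) serial residual
    correlation across repeated measurements, and Normal or identity-link
    Gamma observation families. General coefficients take either vague Cauchy
    priors or the regularized horseshoe shrinkage prior with a closed-form
    global-scale guess. Includes ancestral-sampling prediction, posterior
    predictive checks, NRMSE model comparison, subject-level time-series
    cross-validation with direction-of-change classification, personal-effect
    extraction and k-means clustering with elbow diagnostics, and a synthetic
    long-format study generator mirroring a dietary-intervention design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    rjags,
    coda,
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
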