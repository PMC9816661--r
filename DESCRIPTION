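Package: smorepars
Title: Surrogate-Model Calibration of Agent-Based Vascular Tumor Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibrates stochastic agent-based models (ABMs) of 3D vascular
    tumor growth against bulk tumor-volume time-courses by routing all
    inference through an explicitly formulated ordinary-differential-equation
    surrogate model (the SMoRe ParS strategy). Provides a seeded on-lattice
    simulator of stem/progenitor-driven tumor growth with angiogenesis
    (sprouting, tip migration, anastomosis, perfusion), candidate growth-law
    surrogates (generalized Gompertz, generalized logistic, von Bertalanffy)
    with AIC/BIC model selection, weighted least-squares fitting with
    profile-likelihood confidence intervals and identifiable-combination
    inference, reconstruction of 95% confidence hypersurfaces of surrogate
    parameters over ABM parameter space, set-valued inference of
    data-consistent ABM parameter regions, and 3D tumor morphology metrics
    (box-counting fractal dimension, enclosing-surface area/volume,
    compactness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
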