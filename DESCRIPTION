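Package: autoccu
Title: Autologistic Dynamic Occupancy Models for Opportunistic Detection Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating multi-season (dynamic) occupancy from
    presence-only records of a focal species combined with records of common
    congeners used to infer nondetections. Builds weekly detection histories
    on a grid, fits a Bayesian autologistic dynamic occupancy model in which
    colonization and extirpation depend on the number of occupied neighboring
    cells and on seasonal drought, with time-varying imperfect detection, via
    a Metropolis-within-Gibbs sampler. Includes finite-sample and
    unconditional occupancy summaries, response curves, WAIC, posterior
    predictive (Bayesian p-value) goodness of fit, convergence diagnostics,
    and a synthetic-data generator with exact small-instance posterior
    enumeration for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
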