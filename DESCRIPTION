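Package: nmixterra
Title: Terrain-Driven Abundance of Terrestrial Salamanders via Binomial
    Mixture and Multistate Occupancy Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fine-scale abundance analysis for plethodontid salamanders
    (and similar cryptic, count-surveyed taxa): derives microclimate
    covariates (topographic position and wetness indices, potential
    relative radiation, curvature, distance to stream, NDVI) from a
    digital elevation model; fits Bayesian binomial-mixture (N-mixture)
    abundance models with Poisson, zero-inflated Poisson, and
    detection-random-effect parameterizations by Metropolis-within-Gibbs
    MCMC; runs credible-interval-based covariate selection, posterior
    predictive checks, and leave-one-out cross-validation; projects
    abundance across the landscape; and fits three-state multistate
    occupancy models for demographic cohorts (gravid females, juveniles).
    Includes a seeded synthetic-landscape and survey-data generator with
    the exact generating hierarchy the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
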