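Package: timepriors
Title: Bayesian Observer-Actor Models and Subjective-Prior Reconstruction
    for Interval Timing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing motor-sensory time interval reproduction
    with Bayesian observer-actor models. Constructs discrete experimental
    interval distributions and candidate subjective priors, forward-simulates
    ideal observers with constant or scalar (Weber-like) sensory and motor
    noise under several loss functions, compares observer models by marginal
    likelihood (grid quadrature and Laplace approximation) with Bayesian
    model averaging of predicted response bias and variability, and
    reconstructs subjective priors nonparametrically via Gaussian-process
    interpolated control points sampled with slice-sampling MCMC. Includes a
    seeded synthetic-subject generator reproducing the block structure,
    exact-proportion runs, feedback regimes and trial-retention windows of
    the interval reproduction task, so the full pipeline is testable without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
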