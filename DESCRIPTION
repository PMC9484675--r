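Package: trpsupp
Title: Simulated Psychophysics and Latent-Variable Models of Temporal
    Resolution Power and Spatial Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates observers for four auditory timing tasks and a
    visual spatial-suppression task, runs the adaptive procedures used to
    measure them (a Bayesian adaptive QUEST procedure targeting 82%
    correct and weighted up-down staircases targeting 75%), reduces
    trials to the standard performance indices (motion-direction
    duration thresholds, spatial suppression index, difference limina,
    temporal-generalization response dispersion, rhythm-perception
    thresholds, intelligence-test composites), and fits structured
    covariance models with a from-scratch maximum-likelihood engine:
    confirmatory factor models, fixed-links models with a priori loading
    patterns, latent regressions, robust scaled test statistics, fit
    indices, McDonald's omega, factor scores, and modification indices.
    Includes an end-to-end study pipeline and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
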