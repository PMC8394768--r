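Package: hfbm
Title: Heterogeneous Fractional Brownian Motion Analysis of Single-Particle Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for the statistical analysis of heterogeneous anomalous
    diffusion in two-dimensional single-particle tracking data, motivated by
    live-cell trajectories of intracellular vesicles. Provides ensemble-,
    time- and ensemble-time-averaged mean squared displacement estimators,
    velocity autocorrelation functions, sliding-window estimation of local
    anomalous exponents and local generalized diffusion coefficients,
    slow/fast classification of tracks by maximum excursion or by runs of
    superdiffusive local exponents, and scaled-displacement propagators with
    power-law tail fits. Includes an exact circulant-embedding simulator for
    fractional Brownian motion and a heterogeneous-FBM ensemble generator
    with power-law trajectory durations and duration-coupled diffusivities,
    so every estimator can be validated by parameter recovery on synthetic
    ensembles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
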