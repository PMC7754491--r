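Package: plastevol
Title: Evolution of Phenotypic Plasticity Under Stochastic Salinity Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for experimental evolution of
    phenotypic plasticity in randomly fluctuating environments. Provides
    first-order autoregressive (AR1) salinity-regime simulation with transfer
    recipes and realized-predictability estimation, a synthetic flow-cytometry
    data generator with known plasticity structure, event gating and bead
    calibration, per-capita growth rates with growth-phase labelling,
    redundancy-analysis (RDA) variation partitioning with ANOVA-like
    permutation tests, and a Euclidean reaction-norm plasticity statistic with
    hierarchical nonparametric bootstrap inference. Tidy interfaces throughout:
    data frames in, tibbles out, with tidy(), glance() and autoplot() methods
    for fitted objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
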