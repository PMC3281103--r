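Package: senstep
Title: Stochastic Step Model of Replicative Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models population-level phenotype kinetics (such as mitochondrial
    ROS production measured by MitoSOX fluorescence) in ageing fibroblast
    cultures as a two-component mixture of discrete proliferating and senescent
    cell states. Provides the closed-form mixture expressions and their
    calibration from boundary populations, linear interpolation of
    senescent-fraction-versus-population-doubling curves with uncertainty,
    a per-cell stochastic step simulator, gamma/empirical/digitized phenotype
    distribution machinery including a from-scratch Hartigan dip test of
    unimodality, fluorescence time-course normalisation and model validation,
    marker-based (Ki67, gamma-H2A.X foci) cell classification, and a seeded
    synthetic-study generator so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    fitdistrplus
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
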