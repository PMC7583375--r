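Package: predindex
Title: Spatiotemporal Predation Indices, Synchrony, and Portfolio Effects
    for Groundfish Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds spatially explicit, age-structured indices of predation
    on a focal prey species from standardized survey-style data. Combines
    stock-assessment predator biomass, relative predator densities from
    delta (hurdle) generalized additive models, Wisconsin bioenergetics
    maximum-consumption rations, length- and biomass-weighted gravimetric
    diet proportions, and prey age compositions from von Bertalanffy
    growth into a predation tensor. Provides moving-window variance
    ratios, portfolio effects, consumption anomalies, and
    consumption-to-biomass diagnostics, together with a seeded synthetic
    survey generator for end-to-end validation against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    mgcv,
    nlme,
    nnet,
    minpack.lm,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    ggplot2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
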