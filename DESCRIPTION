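Package: cryptoweather
Title: Global Chemical Weathering by Early Non-Vascular Vegetation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale simulation of chemical weathering driven by
    lichen- and bryophyte-like vegetation under Late Ordovician boundary
    conditions. Provides a synthetic paleoclimate and paleogeography
    generator with stochastic monthly-to-hourly weather disaggregation, a
    trait-sampled (Monte-Carlo species) non-vascular vegetation model
    built on Farquhar photosynthesis with a carbon-concentration
    mechanism, Q10 respiration and a poikilohydric water balance, an
    NPP-to-phosphorus-to-rock-volume weathering conversion with erosion-
    and runoff-based (calcite-equilibrium) limits and a phosphorus
    feedback on productivity, and abiotic/empirical reference models
    (GEOCARB-style scaling, GEM-CO2, Budyko runoff).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
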