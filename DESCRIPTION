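Package: heatptb
Title: Heat Exposure and Preterm Birth: Time-Series, Mediation and
    Additive-Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the association between warm-season
    apparent temperature and daily preterm-birth counts. Constructs a
    humidity-adjusted apparent-temperature exposure with station backfill
    and two-day lag means, multiply imputes missing air-pollutant
    mediators by chained equations, fits spline Poisson time-series
    models for total effects, estimates natural direct effects via
    inverse odds weighting, decomposes attributable fractions into
    direct and indirect components, quantifies additive effect
    modification with the relative excess risk due to interaction
    (RERI) from negative-binomial models on stratum-expanded counts,
    and runs a time-stratified case-crossover sensitivity analysis.
    Includes a seeded synthetic-data generator with recoverable ground
    truth and an end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS,
    survival,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
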