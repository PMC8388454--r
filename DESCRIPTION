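Package: heatrhythm
Title: Heat-Stress Classification and Circadian Behavior Modelling for Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dairy-cow behavior under heat stress from barn
    sensor logs and accelerometer-collar behavior records. Computes the hourly
    temperature-humidity index (THI) from raw temperature/relative-humidity
    readings, accumulates a 24-hour heat load, classifies hours into heat-stress
    strata by heat-load quartiles, compares behavior time budgets between
    no-stress and heat-stress hours by one-way ANOVA, and fits single- and
    double-harmonic circadian models of hourly behavior by nonlinear least
    squares with brute-force grid initialization. Includes a synthetic farm-data
    generator so the full pipeline is testable without proprietary collar data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
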