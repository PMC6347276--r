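Package: vegfire
Title: Desk-Scale Vegetation-Fire-Carbon Scenario Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A gridded ecosystem simulator for exploring how fire-occurrence
    assumptions and the CO2 fertilization effect interact with a warming,
    summer-drying climate to shape wildfire, carbon fluxes, and vegetation
    composition. Implements the daily Canadian Fire Weather Index moisture
    codes (FFMC, DMC, DC, BUI), three alternative fire-occurrence algorithms
    (unlimited ignitions above fuel-condition thresholds, unlimited ignitions
    with suppression, and a three-stage stochastic ignition algorithm with a
    Chapman-Richards initiation probability), a log2 CO2 multiplier on
    production and transpiration, a simplified carbon-pool surrogate with
    exact NPP/NEP/NBP accounting, climate-threshold vegetation typing, and a
    six-scenario factorial runner with common random numbers. Driven entirely
    by a seeded synthetic climate generator emulating maritime seasonality,
    late-century warming, and an RCP 8.5-like CO2 trajectory; no external
    data are required.
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
    ncdf4,
    optparse
Config/testthat/edition: 3
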