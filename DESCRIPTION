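Package: stickyhab
Title: Two-Stage Habitat Suitability Modelling for Sticky-Egg Spawning
    Fish Under Reservoir Drawdown
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify spawning and hatching habitat for
    phytophilic (sticky-egg) spawners such as carp and crucian carp in
    reservoir tributaries. Builds piecewise-linear habitat suitability
    curves for flow velocity, water depth and water temperature, derives a
    water-level-fluctuation suitability index (SI_L) from an egg-deposition
    depth-frequency table and a five-day cumulative stage drop, combines
    per-cell factor suitabilities into spawning and hatching habitat
    suitability indices (HSI), and aggregates weighted usable area (WUA)
    and suitability-class area tables. Includes synthetic generators for
    stage series, two-dimensional hydraulic fields, egg-depth samples and
    larvae-density series, validation diagnostics (lagged correlation,
    Monte-Carlo egg-cohort survival), file readers and writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
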