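Package: pmburden
Title: Population-Weighted PM2.5 Exposure Trends and Attributable
    Mortality Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing long-term change in population-weighted
    fine particulate matter (PM2.5) exposure and its health burden.
    Implements population-weighted exposure aggregation on gridded
    concentration and population rasters, normalization of regional
    exposure to global population, ordinary-least-squares and
    Mann-Kendall trend estimation, GEMM-style concentration-response
    evaluation with population attributable fractions and attributable
    mortality, finite-difference marginal-benefit sensitivity, and an
    order-ensemble (Shapley) decomposition of mortality change into
    exposure, age-structure, baseline-mortality-rate and population
    drivers.  A synthetic scenario generator emulates the gridded
    exposure and population inputs and the demographic tables, so the
    full pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
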