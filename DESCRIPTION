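Package: seamountr
Title: Distance-Effect Models and Movement Analytics for Seamount
    Aggregation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for quantifying how seamounts aggregate
    pelagic life. Fits penalized-spline distance-effect models (negative
    binomial, Tweedie, Gaussian and quasi-likelihood families) and derives a
    derivative-based radius of influence and enrichment magnitude with
    posterior-simulation credible intervals. Companion tools reduce baited
    remote underwater video (BRUV) and visual-transect surveys to response
    variables, classify and integrate hydroacoustic backscatter (NASC),
    compute chlorophyll enrichment indices and tidal periodicity from
    oceanographic series, summarise acoustic-telemetry residency and diel
    behaviour, and test site fidelity of satellite-tracked animals against a
    correlated-random-walk null. A seeded synthetic-data generator emulates
    the statistical structure of every input so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    nlme,
    MASS,
    geosphere,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
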