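Package: duosurvey
Title: Dual-Method Bird Survey Analysis: Diversity, Detection and Protocol Efficiency
Version: 0.1.0
Authors@R:
    person("Robin", "Calloway", email = "robin.calloway@posteo.net", role = c("aut", "cre"))
Description: Tools for analysing paired point-count (PC) and autonomous
    recording unit (ARU) bird surveys along elevational gradients.
    Implements incidence-based Hill-number rarefaction and extrapolation
    with coverage standardisation and Chao2 asymptotic richness,
    family-level single-season occupancy-detection models with a
    first-order Markov autocorrelation covariate and QAIC model selection,
    Fisher exact tests for method bias, and bootstrap cost-efficiency
    analysis of single- and mixed-method survey protocols. Includes a
    synthetic survey-data generator emulating a two-region mountain study
    design so the full pipeline can be exercised and validated without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
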