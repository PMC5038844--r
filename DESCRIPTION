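Package: stomdyn
Title: Dynamic Modelling of Stomatal Conductance, Photosynthesis and
    Intrinsic Water-Use Efficiency Under Fluctuating Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates leaf-level gas exchange under fluctuating light with a
    four-state dynamic model: a representative ('big stoma') pore area relaxing
    towards a light-dependent target, CO2 mole fractions in the intercellular
    airspaces and at the carboxylation sites, and a sugar-accumulation feedback
    that slowly downregulates both stomatal opening and gross assimilation.
    Stomatal pore area is scaled to leaf-level conductance through stomatal
    density and pore geometry, and gross assimilation follows the biochemical
    (Rubisco / electron-transport limited) photosynthesis model. The package
    couples the model to Bayesian calibration against observed assimilation and
    conductance time series (adaptive-covariance warm-up followed by fixed
    random-walk Metropolis, with effective-sample-size and Monte-Carlo
    standard-error diagnostics), one-at-a-time sensitivity scans, step-change
    light experiments with initial-slope and mean-response statistics, and
    generators for synthetic light regimes and noisy observations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
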