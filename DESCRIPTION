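Package: adaptckd
Title: Adaptive Platform Trial Simulation and Bayesian Decision Rules for
    Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and decision engine for a Bayesian adaptive platform
    trial in chronic kidney disease.  Generates virtual cohorts with
    longitudinal eGFR and albuminuria (UACR) trajectories including acute
    reversible and chronic treatment effects, runs the interim-analysis
    state machine (UACR surrogate futility, eGFR-slope futility,
    posterior-probability success with completer gates), and estimates the
    design's operating characteristics (type I error, power, expected
    sample size and time to decision) by Monte Carlo, including success
    threshold calibration with common random numbers.  Also provides the
    2021 CKD-EPI creatinine eGFR equation and long-format cohort CSV I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
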