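Package: gainstudy
Title: Detection and Analysis of Sudden Gains in Weekly Symptom Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sudden gains (large, stable between-session
    symptom decreases) in longitudinal clinical-trial data. Implements the
    three-criterion detection rule built on the Jacobson-Truax reliable change
    index, a sliding-window pooled-standard-deviation stability test, simulation
    of realistic two-arm weekly trajectory cohorts with injected gains and
    linked process measures, mixed-effects contrasts of process measures around
    the gain, outcome-by-gain-status models with baseline adjustment, and the
    blinded videotape-pair rating study design with ICC(2,1) interrater
    reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    emmeans,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
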