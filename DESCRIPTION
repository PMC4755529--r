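Package: afsnapshot
Title: Simulation of Daily Snapshot ECG Monitoring for Atrial
    Fibrillation Detection
Version: 0.1.0
Authors@R:
    person("TRENDS", "Simulation Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the sensitivity of once-daily snapshot ECG rhythm
    monitoring for detecting device-confirmed atrial tachycardia /
    atrial fibrillation (AT/AF) from per-patient daily burden series.
    Detection over a monitoring window is modelled as independent daily
    Bernoulli trials with success probability equal to the fraction of
    the day spent in AT/AF; window-level detection probabilities are
    computed both by Monte Carlo simulation and by the exact
    closed-form complement product. Includes a calibrated synthetic
    cohort generator emulating published burden distributions,
    stratified cohort reporting with exact binomial confidence
    intervals, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
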