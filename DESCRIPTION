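Package: sweatcal
Title: Calibration, Transport Simulation and Accuracy Analytics for
    Passive-Sweat Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis chain of a passive-sweat continuous
    glucose monitor: a seeded synthetic-cohort generator for blood glucose,
    sweat-glucose proxy, sensor potential, CGM and sweat-rate traces; the
    personalized two-point potentiometric calibration that converts sensor
    potential (mV) into sweat-based blood glucose estimates (mg/dL); a
    finite-volume Darcy-Forchheimer flow and convection-diffusion solute
    transport simulator for the wetted paper microfluidic channel; and
    accuracy analytics (MARD, Parkes consensus and Clarke error grids,
    Pearson correlation, onset/peak lag estimation, rate-of-change
    stratified MARD) together with an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
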