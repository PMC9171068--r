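Package: stepclamp
Title: Intrinsic Excitability Analysis for Current-Clamp Step Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction, quality control and two-group statistical
    comparison for whole-cell current-clamp step-protocol recordings from
    neurons. Measures passive membrane properties (resting potential, input
    resistance, membrane time constant, HCN-mediated voltage sag) and active
    properties (rheobase, action-potential threshold and waveform
    morphometrics, firing probability, delay to first spike, instantaneous
    firing frequency and spike-frequency accommodation) from square-pulse
    current injections. Includes an adaptive exponential integrate-and-fire
    simulator with an H-type sag conductance that generates synthetic cohorts
    with exportable ground truth for end-to-end validation, a documented
    plain-text sweep-bundle format, Grubbs outlier screening, and Welch-t /
    Mann-Whitney group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
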