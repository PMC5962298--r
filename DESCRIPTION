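Package: illumdisc
Title: Chromatic Illumination Discrimination: Stimuli, Staircases, and Gaze Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for chromatic illumination
    discrimination psychophysics. Constructs CIELUV illuminant series along and
    orthogonal to the daylight locus, builds tiled stimulus scenes with fixed or
    shuffled reflectance-to-tile assignments, runs interleaved 1-up-2-down
    adaptive staircases on simulated observers, extracts discrimination
    thresholds by maximum-likelihood cumulative-Weibull fitting with a 70.71
    percent criterion, calibrates exclusion rules against a simulated
    random-responder null, and analyses synthetic eye-tracking data with an
    adaptive velocity-based fixation detector, cross-interval overlap
    statistics and trial-shuffled permutation nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
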