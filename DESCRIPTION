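Package: gazemetrics
Title: Oculomotor Metrics for Fixation, Saccade and Smooth-Pursuit Tasks
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for clinical oculomotor analysis of 250 Hz gaze
    recordings: velocity/acceleration-threshold event detection (saccades,
    fixations, blinks), fixation-stability metrics (square-wave jerks, large
    intrusive saccades, longest fixation), gap/overlap saccade metrics
    (time to target, main-saccade selection, latency, amplitude error,
    velocity), sinusoidal smooth-pursuit gain, covariate-adjusted group
    statistics with cluster-robust errors, a greater-than-2-SD impairment
    classifier with accuracy-maximising ROC cut-offs, and a synthetic
    gaze-trace simulator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
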