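Package: rotadapt
Title: Simulation and Analysis of Gradual Visuomotor Rotation Adaptation
    with EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyzes a two-task (visually- vs memory-guided
    reaching) gradual visuomotor rotation experiment. Provides a synthetic
    experiment generator (trial design, state-space learner driven
    trajectories, event-marked multichannel EEG on a 1/f background),
    reach kinematics (zero-phase Butterworth filtering, hand angle at peak
    y-velocity, velocity-threshold reaction and movement times, moving-window
    outlier exclusion), a single-rate state-space model of trial-by-trial
    adaptation with regression estimation of retention and adaptation rates,
    Morlet time-frequency decomposition with decibel baseline normalization
    and canonical band averaging, per-time-point task decoding under
    leave-one-subject-out cross-validation with permutation-based chance and
    significance calibration, and repeated-measures ANOVA with partial eta
    squared plus paired t tests with Cohen's d.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
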