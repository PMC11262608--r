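Package: vgspipe
Title: Visually Guided Saccade Analysis from Binocular Eye-Tracking
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis of visually guided saccades (VGS) recorded
    with a screen-based binocular eye tracker in a gap paradigm.  Converts
    raw 250 Hz gaze-sample exports between pixels and degrees of visual
    angle, runs a velocity-threshold (I-VT) event-detection chain (eye
    averaging, gap-fill interpolation, windowed angular velocity,
    classification, fixation merging, duration filtering, blink detection
    from validity codes), segments recordings into gap-paradigm trials,
    applies trial validity criteria, computes saccadic parameters (latency,
    duration, amplitude, mean and peak velocity, gain) and blink rates, and
    correlates subject-level oculomotor metrics with demographic and
    neuropsychological covariates using Spearman and Pearson statistics
    (with exact permutation p-values at small n).  Includes a synthetic
    oculomotor data generator -- main-sequence saccade kinematics with
    raised-cosine velocity profiles, blinks, data loss, anticipatory
    saccades and a clinical covariate table with controllable
    covariate-kinematics associations -- providing ground truth for every
    pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
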