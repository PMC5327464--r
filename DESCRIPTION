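Package: wheelphys
Title: Locomotion, Hippocampal LFP and Two-Photon Calcium Analysis for
    Head-Fixed Wheel Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for head-fixed awake-mouse experiments on a
    running wheel: quadrature optical-encoder decoding of position and
    speed, behavioural-state segmentation (locomotion, flickering,
    immobility), walking-step extraction from the speed oscillation,
    hippocampal ripple detection and theta-speed profiling from the LFP,
    two-photon movie motion correction, axial-stability probability maps
    with spatial-reshuffling surrogates, delta-F/F and calcium-transient
    detection, population sparseness, and resampling statistics
    (permutation slope test, circular-shift covariance nulls). A
    synthetic-data module emulates all three input streams (encoder
    waveforms, LFP, calcium movies) with known ground truth so the whole
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
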