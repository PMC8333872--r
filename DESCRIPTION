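Package: gazekit
Title: Webcam Gaze Estimation from Facial Landmarks with a Shallow Neural Regressor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for appearance-based eye tracking from webcam facial
    landmarks. Ingests DeepLabCut-dialect landmark tables time-aligned to a
    moving calibration target, or generates equivalent sessions from a
    geometric head/eye/camera simulator; preprocesses them (likelihood
    filtering, spatial balancing on a screen grid, coordinate normalization,
    train/validation/test splitting); trains a 14-200-2 sigmoid feed-forward
    regressor with stochastic gradient descent, momentum and a step-halving
    learning-rate schedule; and evaluates gaze accuracy in pixels and degrees
    of visual angle, including error histograms, per-region error maps with
    neighbor fill, eccentricity regressions and offset density estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    rlang,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
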