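Package: gaitrec
Title: Light-Weight Activity Recognition from Lower-Limb Wearable Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recognises seven activities of daily living (sitting, standing,
    level walking, ramp ascent/descent, stair ascent/descent) from 19-channel
    lower-limb wearable recordings (waist/thigh/shank IMUs plus knee and ankle
    goniometers sampled at 500 Hz). Implements a light-weight pipeline of
    systematic time-domain feature extraction over 25-sample windows with
    five shifted segmentation passes, three-window temporal context stacking,
    and a single-hidden-layer neural network (100 tanh units, 7 independent
    sigmoid outputs) trained by Polack-Ribiere conjugate gradients with a
    Wolfe-condition line search on a cross-entropy plus L2 objective.
    Includes a synthetic gait-circuit simulator, leave-one-subject-out
    evaluation with confusion matrices and per-class F1, broom-style tidiers
    and ggplot2 plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    tidyr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
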