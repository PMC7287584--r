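Package: gaitvar
Title: Gait Variability and Complexity from Force Plates and Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measurement chain for stride-duration variability and gait
    complexity in continuous walking trials. Detects heel-strikes from summed
    vertical ground reaction force (jerk-based candidates gated by a body-weight
    threshold), from a waist-worn inertial measurement unit (Madgwick orientation
    fusion, Ricker-wavelet matched filtering of vertical acceleration), and from
    an ankle-worn unit (sagittal angular velocity troughs with parabolic
    refinement). Computes stride-duration mean, standard deviation and
    coefficient of variation after median-ratio outlier filtering and
    cross-instrument event matching; refined composite multiscale sample entropy
    (RCME) and refined multiscale permutation entropy (RMPE) of the resultant
    waist acceleration over coarseness scales 1 to 80; and test-retest
    reliability and concurrent-validity statistics (absolute-agreement ICC with
    F-based confidence intervals, Bland-Altman bias and limits of agreement,
    root-mean-square coefficient of variation). Includes a synthetic gait-signal
    generator with ground-truth events for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
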