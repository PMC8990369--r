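Package: gazewatch
Title: Estimating Children's Television Viewing Time from Frame-Level
    Face and Gaze Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective measurement of a target child's television
    viewing time from per-frame video-derived observations. Implements the
    three-stage measurement logic (face detection thresholding with ROC
    operating-point selection, target-child verification by embedding
    correlation against an enrollment gallery with track-based identity
    smoothing, and gaze dichotomization via region-conditional angular
    limits with leave-one-family-out calibration), composes the stages into
    per-frame viewing logs and total viewing-time estimates, and provides
    the agreement statistics used to evaluate such systems against
    duration-coded human observation (confusion-matrix metrics, PABAK,
    Cohen's kappa, intraclass correlations with frames nested in families,
    and paired Wilcoxon tests). A synthetic multi-person session simulator
    with known ground truth makes every stage testable without video data
    or trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
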