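Package: gaitcue
Title: Gait-Phase Detection, Freezing-of-Gait Classification and
    On-Demand Cueing from Foot-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for on-demand gait-synchronous cueing in
    Parkinson's disease. Simulates foot-mounted 6-axis inertial recordings of
    normal and freezing-of-gait (FoG) affected walking with ground-truth
    annotations, estimates foot orientation with a complementary filter,
    segments the signal causally into rest/unrest/motion phases, extracts ten
    per-motion-phase gait features with zero-velocity-update stride
    estimation, classifies motion phases as normal or FoG-affected with a
    SAMME AdaBoost ensemble of shallow decision trees, drives an event-based
    cueing controller that converts classified motion phases into electrical
    stimulation pulse trains, and evaluates detection and classification
    against annotations with interval-overlap matching, delay statistics,
    cueing-coverage shares and gait reports.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
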