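Package: gaitkin
Title: Step and Stride Length Estimation from Multi-Sensor Wearable IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pedestrian gait analysis with body-worn low-cost
    inertial/magnetic sensors. Detects foot gait events (heel-strike,
    foot-flat, heel-off, toe-off) from foot-mounted IMU signals using a
    generalized likelihood ratio test and gyroscope peak segmentation,
    tracks lower-limb segment orientations with an Euler-angle Kalman
    filter, computes step and stride lengths by forward kinematics of a
    five-segment skeletal model, and compares the results against
    acceleration-based step-size models and a foot-mounted zero-velocity
    update strapdown filter with Rauch-Tung-Striebel smoothing. A
    parametric treadmill-walk simulator generates seven-sensor IMU logs
    with full ground truth so that every stage of the pipeline can be
    exercised and validated without external recordings.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
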