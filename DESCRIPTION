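Package: imumocap
Title: Predicting Optical Motion-Capture Marker Positions from Wearable
    Inertial Sensors for Gait Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating lower-limb joint kinematics from
    body-worn inertial measurement units (IMUs) by first predicting the
    16 lower-limb conventional-gait-model (Plug-in Gait) marker
    trajectories over a time-normalized gait cycle with a recurrent
    attention network trained under a biomechanics-aware composite loss,
    then computing sagittal hip, knee and ankle angles from the predicted
    markers with the conventional gait model. Includes a kinematically
    consistent synthetic gait simulator (forward kinematics of a
    seven-segment lower-body linkage with analytically derived IMU
    signals), TRC/CSV/JSON readers and writers, Butterworth zero-phase
    filtering, heel-strike segmentation and 101-frame time normalization,
    dynamic-time-warping evaluation, and leave-one-subject-out experiment
    management.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
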