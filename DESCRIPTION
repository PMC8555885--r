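Package: skilledreach
Title: Reach-to-Grasp Kinematics from Mirror-Based Rodent Pose Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the rodent single-pellet skilled reaching
    task recorded with one high-speed camera and angled mirrors. Calibrates
    the direct/mirror view pair from checkerboard correspondences via the
    essential matrix, triangulates hand and digit keypoints into 3D pellet-
    centred trajectories with confidence and reprojection-error filtering,
    segments reach and grasp phases frame by frame, and computes trajectory
    variability, endpoint generalized variance, grasp aperture, hand
    orientation, digit flexion, circular consistency (mean resultant
    length), within-session moving averages, and learner classification by
    chi-squared proportion tests. Includes group-level linear mixed models,
    bootstrap day-contrast estimation, and a synthetic-cohort generator that
    renders ground-truth reaches as two-view keypoint tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
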