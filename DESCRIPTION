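Package: mocap3d
Title: Multi-Camera Calibration, Robust Triangulation and 3D Kinematics for
    Markerless Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for 3D markerless tracking of articulated bodies from
    multi-camera 2D keypoint detections. Provides a reduced pinhole camera
    model with a single radial distortion coefficient, camera calibration
    from calibration-board detections (greedy covisibility-graph
    initialization followed by iterative sparse bundle adjustment with
    robust losses), filtering of 2D keypoint detections (rolling median,
    Viterbi tracking of candidate detections, and a confidence-score
    autoencoder), 3D triangulation (linear SVD, RANSAC pair search, and
    spatiotemporally regularized optimization with limb-length
    constraints), joint-angle extraction via intrinsic Euler decomposition
    of kinematic chains, step-phase estimation, and a synthetic-scene
    simulator for end-to-end validation without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
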