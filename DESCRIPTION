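Package: posevote
Title: Heatmap Voting Pose Decoding and Uncertainty-Weighted 2D-3D
    Keypoint Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for markerless articulated pose estimation from
    joint heatmaps. Decodes per-joint response grids into subpixel 2D
    coordinates with per-axis uncertainties by whole-map voting
    (soft-argmax over axis marginals), provides the shape and pose
    parameter losses of SMPL-style body models (Smooth-L1 shape loss,
    quaternion pose loss, Gaussian negative log-likelihood keypoint
    loss), and corrects 2D keypoints against a 3D body-structure prior
    by iterative uncertainty-weighted rigid alignment (weighted Kabsch
    via singular value decomposition with orthographic depth
    optimization). Includes a synthetic kinematic body model for fully
    reproducible evaluation, MPJPE and Procrustes-aligned MPJPE metrics,
    a Monte-Carlo benchmark harness, COCO-style keypoint JSON input and
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
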