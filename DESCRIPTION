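Package: rtdic
Title: Riesz-Transform DIC Microscopy Conversion and Computational Kinematic
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts single-shot differential interference contrast (DIC)
    microscopy images into self-luminous intensity images by composite
    directional Riesz-transform frequency filtering, and quantifies chiral
    cell morphology and motility from the converted movies: voxel-wise
    structure-tensor geometry (fiber orientation, polarity, fiber and tip
    certainties, retrograde tracing, signed neurite curvature), dense 2D/3D
    Horn-Schunck optical flow with coarse-to-fine pyramids, five-frame
    voxel-wise kinematics (velocity, acceleration, jerk, Frenet frame,
    chirality-signed angular velocity and axial projections), watershed
    segmentation with flow-assisted centroid tracking, and two-tier
    per-trial/across-trial statistics. Includes synthetic phantom generators
    with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
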