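Package: rebavision
Title: Automated Rapid Entire Body Assessment from Multi-Camera Pose Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes Rapid Entire Body Assessment (REBA) ergonomic risk
    scores from per-frame body and face landmark streams such as those
    produced by video pose-estimation systems. Provides joint-angle
    extraction from 33-point body landmarks, head-pose estimation from six
    face landmarks via perspective-n-point with Rodrigues/Euler
    decomposition, the REBA worksheet graders and lookup tables,
    occlusion-resistant fusion of up to three synchronized camera views,
    temporal averaging of per-joint points, risk-band classification, a
    Box-Behnken design generator with linear response-surface modelling,
    and desirability-based optimization of REBA point profiles. A
    synthetic-scene module renders articulated skeletons with prescribed
    joint angles to three pinhole cameras, with occlusion and noise
    injection, providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
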