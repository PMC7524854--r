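Package: liverreg
Title: Rigid Registration and Accuracy Evaluation for Image-Guided
    Laparoscopic Liver Surgery
Version: 0.1.0
Authors@R:
    person("liverreg", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating rigid registration in augmented-reality
    image-guided laparoscopic liver surgery. Implements stereoscopic surface
    reconstruction from pinhole stereo correspondences, semi-automatic rigid
    registration of a preoperative liver model by iterative closest point
    matching with a liver/non-liver segmentation gate, landmark-based target
    registration error (TRE) in millimetre root mean square, and the cohort
    statistics (mean +/- SD, Shapiro-Wilk, pooled and paired t-tests)
    comparing manual with semi-automatic registration. A synthetic-scene
    generator provides liver-like meshes, distractor surfaces, landmarks and
    stereo observations with known ground truth, so the whole pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
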