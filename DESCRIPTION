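Package: suturenav
Title: Accuracy Evaluation for Augmented-Reality Cranial Suture Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate the accuracy of tracked, augmented-reality
    navigation for cranial suture localization in minimally invasive
    craniosynostosis surgery. Provides rigid transforms and named
    coordinate-frame graphs for tracker calibration chains, paired-point
    rigid registration (orthogonal Procrustes) with fiducial and target
    registration error evaluation, triangle-mesh closest-point queries with
    curve projection and arc-length resampling, the area-over-length suture
    delineation error d = S_A / D_L, and a seeded synthetic skull-phantom
    generator so the complete phantom-study pipeline runs end to end
    without tracking hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
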