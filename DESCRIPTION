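Package: gaitmatch
Title: Multi-View Gait Identity Matching from Pose Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies walkers from pose-estimation landmark sequences by
    matching joint-angle time series and inter-angle Spearman rank-correlation
    features with dependent multi-dimensional dynamic time warping (DTW), then
    aggregating per-camera decisions by majority vote. Reads MediaPipe 33-landmark
    and OpenPose/AlphaPose COCO-18 pose outputs, extracts law-of-cosines joint
    angles for whole/upper/lower body-part feature sets, and includes a seeded
    synthetic multi-view gait generator for end-to-end evaluation without
    access-restricted gait databases.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
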