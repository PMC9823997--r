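Package: eggline
Title: Machine-Vision Egg Grading on a Multi-Lane Roller Conveyor
Version: 0.1.0
Authors@R:
    person("Line", "Vision", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for camera-based weight grading of chicken eggs moving on a
    multi-lane roller conveyor. Implements the field-of-view geometry that
    partitions the camera frame into flow-lane regions of interest, an
    HSV-based detection chain (smoothing, background masking, thresholding,
    contour extraction, minimum-enclosing-circle dirt correction and pixel
    counting), motion-triggered per-egg measurement at a trigger line, an
    area-to-weight calibration fitted by ordinary least squares, and EU
    weight-grade assignment. A fully seeded synthetic conveyor-scene
    generator (ellipsoidal eggs, dirt stains, single- or multi-source
    illumination fields, ground-truth manifests) makes the whole pipeline
    testable without factory footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml,
    withr
Config/testthat/edition: 3
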