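Package: plateletdetect
Title: Platelet Detection in Stained Blood Smears with a Multiscale
    Single-Stage Detector
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects platelets -- the smallest blood cells, 2-4 micrometres in
    diameter -- in stained blood-smear images with a YOLO-v3-style single-stage
    convolutional detector implemented natively in R. Provides box geometry
    (IOU, complete IOU, and the combined CIOU+IOU anchor-matching score),
    k-means anchor clustering under IOU distance, Pascal VOC annotation I/O,
    a deterministic synthetic smear generator for offline testing, a
    Darknet-53-style backbone with a baseline 13/26/52 multiscale head and an
    improved 26/52/104 variant for small targets, training with CIOU box loss,
    greedy NMS inference, and VOC-style precision/recall/F1/AP evaluation with
    threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
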