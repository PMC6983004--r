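Package: strawdetect
Title: Colour-Opponent Early-Fusion Detection of Fruit in Field Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A one-stage anchor-based fruit detector for field imagery built
    around a colour-opponent (CIELab) front end. RGB input is converted to
    CIELab under the D65 illuminant and fused depth-wise with the original
    RGB channels into a six-channel tensor that feeds a compact
    ResNet-18-style backbone with a five-level feature pyramid and shared
    classification/regression sub-networks trained with the focal loss.
    Includes the full detection evaluation protocol (IoU matching,
    precision/recall/F1, average precision, non-maximum suppression,
    false-positive decomposition curves), COCO-style annotation IO with
    viewpoint-aware splits, and a deterministic synthetic scene generator
    producing annotated strawberry-like scenes so the whole pipeline can be
    trained and validated at desk scale on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
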