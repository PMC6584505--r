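Package: cryopick
Title: Single-Shot Convolutional Particle Picking for Cryo-EM Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies a grid-regression convolutional detector for
    localizing single particles in cryo-electron micrographs. One forward pass
    over a (possibly patched) micrograph yields per-grid-cell objectness and
    bounding-box regression, decoded into particle coordinates. Includes the
    detection loss with coordinate regression, training-time image
    augmentation, patch-based inference with non-maximum suppression,
    precision-recall/IOU evaluation, readers and writers for MRC2014
    micrographs and EMAN1/RELION coordinate files, and a parameterized
    synthetic-micrograph generator (planted particles, structural and shot
    noise, contrast transfer function) so the whole pipeline can be trained
    and validated with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    tiff,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
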