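Package: ihcdetect
Title: Immune Cell Detection and Quantification in Immunohistochemistry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts immunohistochemically stained immune cells
    (e.g. CD3/CD8/CD20 positive lymphocytes) in digitised tissue images. A
    patch-based convolutional neural network, trained on 46x46 pixel RGB
    patches, produces a per-pixel likelihood map of positive staining; a fast
    radial symmetry transform converts likelihood blobs into individual
    cell-centre detections. The package includes a synthetic stained-tissue
    image generator with known ground truth (DAB-brown cells on a
    hematoxylin-tinted background with anthracotic pigment, erythrocyte and
    diffuse-stain confounders), patch extraction with mirror/rotation
    augmentation and hard-negative mining, exact dense sliding-window
    inference, and evaluation statistics: per-class confusion rates,
    detection-to-truth matching, and multi-observer relative count
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
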