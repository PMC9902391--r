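Package: dicascade
Title: Automatic Dicentric Chromosome Identification with a Two-Stage CNN Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automatic identification of dicentric
    chromosomes (DICs) in Giemsa-stained metaphase images, the gold-standard
    biomarker for biological radiation dosimetry. Provides metaphase-spread
    locating in low-magnification field images by Otsu thresholding and
    morphological pore-texture suppression, chromosome extraction from
    high-magnification images by k-means binarization, rule-based triage of
    detected objects on width (WH) and internal-hole count (IH), seed-filtered
    watershed splitting of adhesive chromosome masses, and a two-stage
    convolutional neural network cascade in which a second-stage network
    re-screens first-stage positives to suppress false positives of the rare
    DIC class. A seeded synthetic-microscopy generator renders field images,
    metaphase spreads and labelled chromosome tiles with per-object ground
    truth so that every stage is testable without slide data. Includes
    confusion-matrix evaluation (accuracy, sensitivity, specificity, PPV,
    NPV) and analytic cascade false-positive-rate projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
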