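Package: kinetoforge
Title: Forward Modeling of Fluorescence Microscopy Images for the Yeast
    Kinetochore and rDNA Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic widefield fluorescence microscopy images
    from parametric three-dimensional models of the budding-yeast mitotic
    spindle/kinetochore and of the rDNA locus (a bead-spring polymer with
    transient crosslinking), renders them through a Gaussian
    point-spread-function microscope simulator with a camera noise model,
    and reproduces the downstream analysis chain: maximum-projection
    preprocessing, foci detection and extraction of thirteen image
    features, PCA-loading-based feature-importance ranking validated by
    repeated Gaussian-kernel SVM classification, and a small convolutional
    neural network (implemented natively) that classifies images into
    model-parameter classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite,
    xml2,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
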