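Package: deepdemons
Title: Two-Layer Adaptive Diffeomorphic Demons Registration with a CNN
    Rotation Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deformable image registration for 2D images and 3D volumes
    under very large rotations and deformations.  A convolutional
    neural network trained on difference images classifies the rotation
    between fixed and moving image; scale and translation are estimated
    from intensity moments; the rectified pair is then registered by
    diffeomorphic log-demons (stationary velocity fields, exponential
    map by scaling and squaring, Gaussian fluid/diffusion
    regularisation, three-level coarse-to-fine).  Preregistration and
    demons alternate in an outer loop until convergence.  Similarity
    can be measured by SSD, Pearson, Spearman or Kendall correlation,
    plain or on PCA projection scores, in 2D and (triplanar) 3D.  A
    synthetic-data module generates phantoms and ground-truth warps so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
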