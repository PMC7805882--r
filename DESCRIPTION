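Package: beetag
Title: Labeled Honeybee Marker Image Synthesis with Label-Preserving
    Adversarial Augmentations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates realistic, automatically labeled images of the
    circular 12-bit binary markers used to identify honeybees in hive
    monitoring.  An idealistic parametric renderer produces a binary
    marker image, background mask and depth map from a known code and
    pose; a chain of differentiable, range-restricted augmentation
    stages (blur, lighting, background, detail) is trained adversarially
    against unlabeled imagery so that the augmented images look real
    while the bit labels are preserved by construction.  Includes
    hand-designed augmentation baselines, dataset generation with
    discriminator-score filtering, and a residual-network decoder
    trained and evaluated on the mean Hamming distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
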