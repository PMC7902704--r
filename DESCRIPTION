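Package: tlsimage
Title: Tree Species Classification from Laser-Scanning Point Clouds via
    Multi-View Depth Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns individual-tree terrestrial laser-scanning (TLS) point
    clouds into sets of depth-encoded 8-bit grayscale images (ten
    orthographic views per tree, 150 x 100 pixels, farther points drawn
    lighter), balances under-represented species by point-cloud and
    image-space augmentation, trains a compact LeNet-style convolutional
    neural network on a strict per-tree train/test split, and reports
    row-normalised confusion matrices and overall accuracy. Includes a
    seeded procedural generator of conifer and broadleaf tree point clouds
    so the whole pipeline can be exercised without field data, and the
    input-preparation steps (lowest-30% trim, fixed-size point samples)
    used for PointNet-style baselines. The CNN engine is implemented in
    compiled code with no external deep-learning dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
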