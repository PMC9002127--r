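Package: fetalhc
Title: Anchor-Free Rotated-Ellipse Detection for Fetal Head Circumference
    Measurement in 2-D Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-stage, anchor-free detection of the fetal skull as an oriented
    ellipse in 2-D ultrasound standard planes, with direct head-circumference
    (HC) measurement from the decoded semi-axes. Implements center-point
    Gaussian heatmap encoding with a variant focal loss, sub-pixel center
    offsets, semi-axis regression, soft stagewise regression (SSR) of the
    rotation angle, and a Kullback-Leibler divergence loss that embeds
    oriented ellipses as 2-D Gaussians to couple center, axis and angle
    gradients. A compact CPU U-shaped encoder-decoder with optional
    bottleneck/decoder multi-head self-attention produces the stride-4 head
    maps; a seeded ultrasound skull-phantom generator, the matching
    augmentation grid, negative-sample construction, and MAE/ME,
    rotated-ellipse average precision and Bland-Altman evaluation complete
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
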