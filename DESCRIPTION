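Package: mpmtumor
Title: Segmentation and Discrimination of Breast Fibroepithelial Tumors in Multiphoton Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computer-aided differentiation of breast fibroadenoma from
    phyllodes tumor on label-free multiphoton microscopy images. Provides a
    synthetic two-channel (second harmonic generation + autofluorescence)
    image generator with ground-truth epithelial/stroma/outer masks, a
    compact SegNet-style encoder-decoder for pixel-wise three-class
    segmentation trained by stochastic gradient descent with momentum,
    segmentation evaluation (total accuracy, per-class and area-weighted
    intersection over union, difference images), per-image morphometric
    scores (epithelial-to-stromal area ratio, mean stromal SHG intensity),
    two-sample Kolmogorov-Smirnov group comparison, Fisher linear
    discriminant analysis over full images and 128-pixel blocks, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
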