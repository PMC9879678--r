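Package: semdeblur
Title: Semisupervised Adversarial Deblurring of Serial Scanning Electron
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Blind restoration of defocused and astigmatic scanning electron
    microscopy (SEM) micrographs, aimed at connectomics preprocessing where
    blurry serial sections degrade downstream neuron segmentation.  Provides a
    progressive multi-scale decoding generator with hybrid feature extractors,
    a least-squares adversarial discriminator, differentiable augmentation of
    discriminator inputs, and a semisupervised objective that exploits
    unlabeled blurry micrographs.  Includes a synthetic myelinated-axon
    phantom and defocus/astigmatism blur simulator, PSNR/SSIM/adapted-Rand
    quality metrics, tiled inference for large micrographs, and a small
    reverse-mode automatic differentiation engine for convolutional networks
    implemented with 'Rcpp'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
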