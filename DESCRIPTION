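Package: srcycle
Title: Unpaired Super-Resolution of Lung CT to Micro-CT Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains and evaluates an unpaired super-resolution model that
    maps low-resolution clinical lung CT patches onto the intensity and
    texture scale of micro-CT, using two asymmetric cycle-consistent
    generators (an upscaling generator with sub-pixel shuffling and a
    downscaling generator), least-squares adversarial objectives, and a
    multi-modality super-resolution (MMSR) loss built from SSIM, downsample
    and upsample consistency terms. Includes CT intensity normalization,
    lung masking by region growing, patch extraction, a seeded synthetic
    lung-phantom generator for both domains, a PSNR/SSIM evaluation
    protocol based on bicubic degradation, and tiled whole-slice inference.
    The convolutional engine (convolutions, normalization layers, sub-pixel
    shuffling, Adam) is implemented in R with Rcpp kernels and exact manual
    backpropagation, so training runs on a plain CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
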