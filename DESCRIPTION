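Package: hyperstain
Title: Virtual EVG Staining of Hyperspectral H&E Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for converting 61-band hyperspectral images of
    hematoxylin-and-eosin (H&E) stained tissue into realistic 3-channel RGB
    Elastica van Gieson (EVG) stained images. Provides transmittance
    calibration of hyperspectral cubes, dye-basis spectral projection and
    sRGB rendering via color-matching functions, feature-based affine
    registration of ground-truth EVG tiles, a heterogeneous-modality
    CycleGAN (61-to-3 and 3-to-61 channel U-Net generators with PatchGAN
    discriminators) trained with a basis-function identity loss, a
    supervised refinement phase on paired tiles, image-quality metrics
    (SSIM, PSNR, RMSE, fibrous-region RMSE via HSV masking), and a
    synthetic phantom generator producing paired two-dye Beer-Lambert
    cubes for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    MASS,
    png,
    Rcpp,
    stats,
    tiff,
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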