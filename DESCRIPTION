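Package: poroct
Title: Dual-Resolution X-Ray CT Porosity and Microstructure Analysis of
    Fruit Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the internal gas-filled pore space of fruit from
    X-ray computed tomography at two resolutions. Provides a two-point
    grey-value to porosity calibration anchored on juice (0%) and air
    (100%) references, segmentation of individual fruits and their
    anatomical regions (cortex, core, seeds, cavities) from low-resolution
    scans, voxelwise porosity mapping with slice maps and line profiles,
    high-resolution cell and pore morphometrics (Otsu thresholding,
    watershed blob splitting, equivalent-sphere diameters, cell density),
    a PCA-loading-weighted composite quality index with anatomy-based
    radar-chart export, and synthetic phantom generators (fruit scenes,
    packed-cell volumes, latent-factor quality tables) with exact ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
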