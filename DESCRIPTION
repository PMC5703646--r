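Package: caclean
Title: CLEAN-Based Detection of Calcium Release Sites in Cardiomyocyte
    Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, maps and characterises individual
    excitation-contraction-coupling (ECC) couplon sites from fast
    confocal recordings of the upstroke of electrically evoked calcium
    transients. The method adapts the astronomical CLEAN deconvolution
    to calcium imaging: the purely diffusive evolution of fluorescence
    between consecutive frames is predicted with a two-dimensional
    diffusion kernel and subtracted, and the remaining newly released
    signal is decomposed by iterative subtraction of small
    diffusion-shaped objects whose centres accumulate into a couplon
    map. Includes watershed segmentation of the maps, couplon
    statistics (FWHM, density, re-fire rate, firing probability,
    temporal and spatial coefficients of variation, structure-only
    SSIM, FFT periodicity, 3D stacking), a synthetic-data generator
    for elementary calcium release events with Poisson-Gaussian camera
    noise, and the calibration and validation experiments built on it.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
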