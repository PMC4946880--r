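Package: scanfcs
Title: Scanning Fluorescence Correlation Spectroscopy and SHR-SCR Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scanning fluorescence correlation spectroscopy analyses for
    confocal raster and line scans of fluorescently tagged proteins: raster
    image correlation spectroscopy (RICS) with a 3D Gaussian diffusion model,
    pair correlation function (pCF) barrier analysis with an automated
    Movement Index, number-and-brightness (N&B) oligomer analysis with
    S-factor calibration, and two-colour cross-N&B complex stoichiometry.
    Includes a Brownian-dynamics raster-scan simulator with known ground
    truth, a six-variable ODE model of SHORTROOT/SCARECROW dynamics in the
    Arabidopsis root, Sobol total-effect sensitivity analysis, and
    coordinate-descent calibration of the model against N&B-derived
    composition constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
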