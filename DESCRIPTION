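Package: pattwin
Title: Digital-Twin Photoacoustic Thermometry for Laser-Heated Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates photothermal heating of voxelized ex vivo tissue phantoms and
    reconstructs the internal temperature field from photoacoustic observations.
    Provides Monte-Carlo photon transport and a diffusion solver for the optical
    fluence, an explicit finite-difference bioheat solver with its state-space
    transition matrix, a delay-and-sum photoacoustic forward model with universal
    back-projection reconstruction, Grueneisen-based photoacoustic thermometry with
    water-bath calibration, and Kalman-filter fusion of model predictions with
    photoacoustic temperature measurements, extending temperature estimates to
    points carrying no photoacoustic signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
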