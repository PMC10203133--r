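Package: tomorest
Title: Knowledge-Transfer Restoration of Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restores cryo-electron tomograms degraded by noise and the
    missing wedge by learning a mapping from simulated (or subtomogram-
    averaging derived) low-quality volumes to their high-quality ground
    truth. Provides an elastic-network normal-mode generator of continuous
    conformations for pseudo-atomic models, a complete cryo-ET forward
    model (tilt-series projection, CTF modulation with phase flipping,
    Gaussian noise injection, weighted back-projection reconstruction,
    missing-wedge geometry), training-pair factories, a self-contained 3D
    U-Net trained by backpropagation, tiled whole-tomogram prediction, and
    quantitative evaluation (region-based SNR in dB, Pearson correlation,
    Fourier wedge occupancy, template matching with coordinate-offset
    statistics). Reads and writes MRC volumes, STAR orientation tables,
    PDB models and IMOD-style tilt files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    bio3d,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
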