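Package: lsphase
Title: Two-Band Learned Synthesis for Quantitative Phase Retrieval at Low Photon Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for coherent defocused-intensity
    phase imaging in the photon-starved regime. Provides a discrete Fresnel
    (angular-spectrum) forward model with Poisson/Gaussian noise, the
    single-iteration Gerchberg-Saxton approximant, power-law spectral
    pre-filtering and power spectral density diagnostics, a seeded generator of
    phase objects with natural-image (inverse power law) spectra, and the
    learning-to-synthesize (LS) reconstruction scheme: three residual U-nets
    (low band, high band, synthesizer) trained with the negative Pearson
    correlation loss, plus histogram-matching phase calibration and a
    quantitative evaluation harness (PCC, PSNR, SSIM, spectral comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    tiff,
    png,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
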