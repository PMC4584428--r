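Package: icemotion
Title: Beam-Induced Motion of Water in Amorphous Ice from Dose-Fractionated Cryo-EM Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of dose-fractionated electron cryo-microscope movies of
    amorphous ice: noise-whitened power spectra, circularly averaged Thon-ring
    curves, block-summed spectra as a function of frames per block, and a
    Gaussian-Markov model of beam-induced molecular motion whose fit yields the
    per-electron mean-squared displacement of water molecules, the optimal
    electron exposure per image for observing Thon rings, and the Brownian-blur
    B-factor expected for embedded macromolecules.  Includes a stochastic
    detector model (gain statistics, DQE, aliased noise-power spectrum), a
    particle-based and a Fourier-domain movie simulator, and minimal MRC/MRCS
    input/output, so that every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
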