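Package: nucleospec
Title: UV-Spectrophotometric Characterization of Nucleoside Phosphorylase Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Inference machinery for UV-spectrophotometric characterization of
    nucleosides and nucleoside phosphorylase (NP) chemistry. Provides
    Beer-Lambert extinction calibration and calibration transfer through
    isosbestic points, isosbestic-normalized two-state spectrophotometric pKa
    determination, continuous two-wavelength monitoring of reversible
    glycosylation/phosphorolysis reactions with equilibrium-constant
    estimation, initial-rate Michaelis-Menten kinetics with AICc model
    discrimination, and assembly of predicted UV spectra from tabulated
    excited-state calculations by Boltzmann weighting and Gaussian broadening.
    A forward simulator generates plate-reader-like synthetic data for every
    stage so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
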