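Package: specmap
Title: Spectroscopic Maps and Anharmonic Frequencies for Terminal Alkyne
    Vibrational Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the vibrational frequency of terminal
    alkyne probes in solution. Implements a sinc-basis discrete variable
    representation (DVR) solver for one-dimensional anharmonic
    vibrational problems, a frequency decomposition analysis that
    attributes frequency shifts to individual interaction-energy
    components of a decomposed potential, an electric-field plus
    repulsive Lennard-Jones spectroscopic map with published
    coefficients for alkynes in triethylamine, cylindrical distribution
    functions and nitrogen-association kinetics for solvation-structure
    analysis, and Raman lineshapes from fluctuating-frequency
    trajectories. Ships a synthetic-fixture generator so every analysis
    can be exercised with known ground truth and no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
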