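Package: forcefret
Title: Single-Molecule FRET Force-Sensor Analysis for TCR Pulling Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of molecular tension-sensor experiments read out by
    single-molecule FRET under alternating laser excitation. Converts
    two-colour image stacks into localizations, trajectories and
    background-corrected brightness triplets, applies the photobleaching and
    stoichiometry quality filters, computes corrected FRET efficiency and
    stoichiometry, calibrates the flagelliform spring sensor to piconewton
    forces, fits FRET populations with Gaussian mixtures, and provides
    kinetic, diffusion and mobility analyses. A synthetic-movie generator
    with full ground truth (EMCCD noise model, Gaussian point-spread
    functions, Brownian motion, single-step photobleaching) makes every
    stage verifiable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    mclust,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
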