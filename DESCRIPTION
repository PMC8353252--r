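Package: poredyn
Title: Confined Water and Ion Dynamics in Peptide Nanotube Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular trajectories of species confined
    in transmembrane self-assembled cyclic peptide nanotubes: pore residency
    classification, survival probability and residence half-life estimation,
    windowed velocity statistics with Freedman-Diaconis binning, positional
    probability heatmaps in Cartesian and cylindrical coordinates,
    contribution-decomposed radial distribution functions with coordination
    number accounting, and geometric hydrogen-bond counting.  Includes a
    synthetic generator of confined Brownian trajectories in a star-modulated
    cylindrical pore with exponential dwell kinetics, providing ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
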