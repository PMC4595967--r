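Package: cofluct
Title: Co-Fluctuation Analysis of Location-Specific Neural Firing on Linear Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tetrode recordings of spatially modulated
    neurons (hippocampal place cells and visual cortical cells) during
    back-and-forth running on a linearized track. Provides position
    linearization and lap segmentation, occupancy-normalized firing rate
    curves, Skaggs spatial information measures, a circular-shuffle spatial
    modulation index (SMI), firing-field detection, Poisson-normalized
    spike-count cross-correlograms, prospective/retrospective bidirectional
    firing classification, and lap-by-lap "noise correlation" of within-field
    firing rate and center-of-mass fluctuations between cell pairs, with
    behavioral covariates (running speed, head direction) regressed out.
    Includes an inhomogeneous-Poisson session simulator with known ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
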