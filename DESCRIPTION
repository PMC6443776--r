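Package: silkstruct
Title: Hierarchical Structure and Mechanics of Silk Fibres from X-Ray
    Scattering, Tensile and Sequence Data
Version: 0.1.0
Authors@R:
    person("silkstruct", "developers", role = c("aut", "cre"),
           email = "silkstruct@example.org")
Description: Analysis chain for hierarchically ordered protein fibres:
    wide-angle X-ray diffraction crystallinity, unit-cell and crystal-strain
    analysis; small-angle X-ray scattering long-period harmonics,
    electron-density correlation-function decomposition and Scherrer bundle
    sizing; tilt-corrected tensile mechanics; and mapping of
    polyalanine-block tandem-repeat protein architecture onto the
    crystalline/amorphous phase structure. Ships a forward model for every
    input (scattering profiles, fibre diagrams, tensile logs, repeat-motif
    sequences) with recorded ground truth, so every analysis stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
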