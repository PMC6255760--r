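Package: helicard
Title: Helical Symmetry and Interface Analysis for CARD Filaments
Version: 0.1.0
Authors@R:
    person("helicard", "developers", email = "helicard@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing helical filaments formed by
    caspase-activation-and-recruitment domains (CARDs) and other death-fold
    modules. Builds filament models from a monomer and a screw symmetry
    (axial rise, azimuthal twist), computes pitch and protrusion-spacing
    arithmetic, simulates noisy 2D projection micrographs, estimates the
    helical rise from meridional layer-line profiles, classifies
    inter-subunit contacts into the death-fold Type I/II/III interfaces,
    and predicts the categorical outcome of charge-reversal interface
    mutations. Includes a synthetic pseudo-atom CARD generator so the whole
    pipeline is testable without any deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
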