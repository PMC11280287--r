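Package: ivptr
Title: In Vitro Permeation Testing Analysis for Franz Diffusion Cell Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Analysis pipeline for in vitro permeation testing (IVPT) of
    transdermal drug delivery in Franz diffusion cells, with emphasis on
    microneedle-assisted delivery. Converts sampled receptor-chamber
    concentrations into cumulative permeation profiles with the
    withdrawal-and-replacement correction, estimates steady-state flux and
    lag time from the terminal linear segment, and derives permeability and
    diffusion coefficients, predicted steady-state plasma concentrations,
    dense-microchannel flux extrapolations and required array sizes.
    Companion modules summarise microchannel geometry, skin-integrity
    measurements (electrical resistance, transepidermal water loss), skin
    disposition and topical selectivity, and oscillatory rheology sweeps.
    A Fickian Franz-cell simulator with known ground truth supports
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
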