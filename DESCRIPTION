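Package: oligoscreen
Title: Non-Targeted Screening of Oligoesters in Biodegradable Polyester Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for non-targeted screening of additives and non-intentionally
    added substances (NIAS) in biodegradable polyester mulch films. Provides
    exact-mass arithmetic for elemental formulas and electrospray adducts, a
    combinatorial predicted database of cyclic and linear oligoesters built from
    lactate, butylene adipate, butylene terephthalate and butylene sebacate
    repeat units, extraction of oligomer ion ladders from direct-infusion
    high-resolution mass spectra, LC-MS/MS diagnostic-fragment annotation with
    Schymanski-style confidence levels, copolymer composition from 1H NMR
    integrals, internal-standard GC quantification, and seeded synthetic-data
    generators for validating every stage without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
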