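Package: DeuteR
Title: Quantification of Molecular Deuteration by Isotopologue
    Deconvolution of High-Resolution Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines the degree of deuteration of an isotopically
    enriched small molecule from a high-resolution mass spectrum.  Given
    the molecular formula of the fully deuterated compound and an
    electrospray adduct (explicit or auto-selected), the package predicts
    the isotopic fine structure of every deuterium isotopologue, extracts
    signals from a delimited-text spectrum at the predicted target masses,
    and deconvolves them with the compound's isotopic pattern as a
    response function to recover the isotopologue probability
    distribution and the overall percent deuteration.  A first-order
    site-class model of hydrogen/deuterium back-exchange and a profile
    spectrum renderer are included so the whole pipeline can be exercised
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'isotopes.R'
    'formula.R'
    'adduct.R'
    'pattern.R'
    'spectrum-io.R'
    'grid.R'
    'deconvolve.R'
    'pipeline.R'
    'report.R'
    'hdx-sim.R'
    'cli.R'
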