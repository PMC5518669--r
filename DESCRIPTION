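Package: oxbilayer
Title: United-Atom Bilayer Construction and Analysis for Oxidized Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds united-atom POPC/cholesterol bilayer model systems containing
    lipid peroxidation products (hydroperoxide and chain-cleaved aldehyde species),
    and analyses bilayer trajectories for the standard structural observables:
    area per lipid with block-averaged error bars, bilayer thickness from the
    phosphate density profile, deuterium order parameters of the palmitoyl chain
    with geometric deuterium reconstruction, mass density profiles, core water
    density, and transmembrane water-pore detection. Includes a synthetic-bilayer
    generator with exact ground truth for every observable, so the full analysis
    battery is testable without molecular dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
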