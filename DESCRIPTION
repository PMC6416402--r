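Package: conflock
Title: Conformational-Lock Analysis of Dimeric Enzyme Interfaces from Steered-Pulling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect how the two subunits of a homodimeric enzyme
    (modelled on Cu,Zn-superoxide dismutase) are held together and how they
    let go under a steered pull. The package classifies inter-chain contacts
    (hydrogen bonds, hydrophobic contacts, salt bridges) from PDB structures,
    aggregates per-residue-pair short-range Coulombic and Lennard-Jones
    interaction-energy time series into summary tables, detects per-pair
    rupture times and groups pairs into conformational locks, and estimates
    the minimal number of dissociation steps from residual-activity kinetics
    via the Poltorak relations. A parametric trace generator and a
    one-dimensional constant-velocity pull simulator with breakable bonds
    supply every input the pipeline needs without a molecular-dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
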