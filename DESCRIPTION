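Package: cdftkit
Title: Conceptual DFT Reactivity Descriptors and Drug-Likeness Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes chemical-reactivity descriptors from electronic-structure
    summaries of molecules, aimed at computational peptidology workflows.
    Validates frontier-orbital energies against total-energy differences via
    the Koopmans-in-DFT (KID) descriptors, derives the global conceptual-DFT
    descriptors (electronegativity, hardness, softness, electrophilicity,
    electrodonating/electroaccepting powers, net electrophilicity,
    nucleophilicity index), condenses local reactivity to atoms (Fukui
    functions, dual descriptor, Parr functions and their difference), predicts
    pKa from global hardness via an affine model, and profiles drug-likeness
    from SMILES (physicochemical descriptors, bioavailability-radar axes,
    Lipinski and Veber rules). Includes a validated JSON record format, a
    synthetic-record generator with exact population sum rules, and a
    command-line report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
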