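Package: spmekfw
Title: Structure-Based Prediction of SPME/PDMS-Water Partition Coefficients
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts equilibrium partition coefficients (Kfw) of neutral
    organic compounds between polydimethylsiloxane (PDMS) solid-phase
    microextraction (SPME) coatings and water from molecular structure.
    Parses a SMILES subset into hydrogen-suppressed molecular graphs,
    computes the first-order valence molecular connectivity index, an
    additive group-contribution polarizability and a hydrogen-bonding
    indicator variable, fits and reproduces published single- and
    multi-descriptor regression models for log10 Kfw, validates them on a
    test set, and computes equilibrium SPME extraction masses from the
    partition coefficient and phase volumes. Ships a curated 61-compound
    training table and 26-compound test table as fixtures together with a
    consistency checker that flags the documented discrepancies between
    printed and recomputed descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
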