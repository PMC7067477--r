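Package: diffcontact
Title: Difference Contact Maps and Differentially Stabilizing Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two conformations of the same protein through their
    residue-residue contact maps. Contacts are defined on side-chain heavy
    atoms (glycine falls back to the C-alpha atom) with a 5 Angstrom
    threshold; the two maps are subtracted to give the set of contacts
    unique to each conformation, which is then filtered by the change in
    inter-residue distance to retain only contacts associated with large
    scale motion. Residues taking part in the surviving contacts are
    reported as differentially stabilizing residues (DSRs), candidate
    modulators of the conformational equilibrium. Includes SEQRES-based
    residue pairing with coordinate correction and a sequence-identity
    compatibility check, C-alpha superposition RMSD, summary statistics,
    inter-domain contact classification, a synthetic two-conformation
    fixture generator with machine-readable ground truth, and a small
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
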