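Package: contactqa
Title: Evaluation of Predicted Residue-Residue Contacts and Contact-Based
    Decoy Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate predicted residue-residue contacts against
    native protein structures and to use satisfied predicted contacts for
    quality assessment of decoy ensembles. Implements the standard C-beta
    (C-alpha for glycine) 8 Angstrom contact definition with short/long
    sequence-separation classes, top-L/k precision, the contact spread
    metric, secondary-structure-category breakdowns, effective sequence
    number (Neff) of a multiple sequence alignment with an
    inverse-regression confidence interval, Kabsch superposition and a
    fixed-correspondence TM-score, a naive satisfied-contact decoy
    classifier with ROC analysis, ensemble enrichment and
    modelling-failure detection, plus fully seeded synthetic generators
    (native structures, decoy ensembles, prediction lists with controlled
    precision and spread, alignments with known Neff) that make every
    stage testable at desk scale. Readers and writers are provided for
    PDB (single chain), CASP RR contact lists, square score matrices,
    FASTA/A3M alignments, three-state secondary-structure strings and
    decoy score tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
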