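Package: epifoot
Title: Structural Epitope Footprinting and Binding Kinetics for
    Antibody-Receptor Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Buried-surface-area epitope footprinting of antibody-antigen
    complexes with chain partitioning, geometric classification of interface
    contacts (hydrogen bonds, hydrophobic, pi-stacking, cation-pi), rigid-body
    superposition with RMSD and TM-score, footprint-overlap quantification
    between binding sites mapped onto a common reference numbering,
    intersection of population sequence variants with a structural epitope,
    and global 1:1 Langmuir plus steady-state fitting of biolayer
    interferometry binding data. Includes deterministic synthetic generators
    (toy two-chain complexes with planted contacts, receptor-family multiple
    sequence alignments with variant tables, simulated biosensor dilution
    series) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
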