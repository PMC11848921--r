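Package: pnaladder
Title: Enzyme-Free PNA Primer-Extension Sequencing by MALDI Mass Ladders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and decoding toolkit for enzyme-free sequencing of
    DNA and xeno nucleic acids (l-DNA, LNA, PNA) by templated synthesis with
    peptide nucleic acid (PNA) 4-mers.  Provides exact elemental-composition
    and monoisotopic-mass arithmetic for PNA oligomers, isotope-envelope
    computation, 4-mer reagent-library combinatorics with antiparallel
    complement pairing, a kinetic simulator of cyclic primer extension with
    reversible azide termination and mismatch competition, a synthetic
    centroided MALDI peak-list generator with adduct and oxidation
    satellites, and a decoder that reconstructs the template sequence from
    the single-residue mass increments of a primer-deletion product ladder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
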