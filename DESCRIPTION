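Package: acpmine
Title: Composition-Based Mining and Design of Anticancer Peptides from
    Metagenomic Reads
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: In-silico derivation of anticancer peptide (ACP) candidates
    from metagenomic sequencing reads. Provides six-frame translation of
    DNA reads into peptide fragments, sliding-window candidate
    enumeration, mono- and dipeptide composition features with
    Bonferroni-corrected discriminative feature selection, a linear
    soft-margin classifier producing calibrated ACP scores,
    physicochemical characterization (elemental formula, average mass,
    net charge, isoelectric point, GRAVY, hydrophobic moment), windowed
    antimicrobial-propensity region scanning, and rational N- or
    C-terminal extension search. A seeded synthetic-data generator
    produces labelled peptide classes with controlled composition shifts
    and DNA reads with planted open reading frames, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
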