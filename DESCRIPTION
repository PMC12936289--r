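Package: mspkit
Title: Mutation-Guided Selection of Mutated Surface Protein Antibody Targets
Version: 0.1.0
Authors@R: person("mspkit", "maintainers", email = "mspkit@example.org",
    role = c("aut", "cre"))
Description: Tools for turning somatic missense variant calls into
    antibody-target candidates. Reads MAF-dialect variant tables, resolves
    each variant against a protein annotation store carrying sequences,
    membrane topology features and subcellular-location labels, classifies
    the mutated residue's compartment, calls mutated surface proteins
    (MSPs: extracellular residue or secreted protein), designs paired
    mutant/wild-type peptide windows with a C-terminal cysteine conjugation
    tag, selects deterministic oligoclonal target panels, and computes
    cohort-level mutation burden and inter-patient sharing statistics.
    Includes a synthetic proteome and tumor-cohort generator with recorded
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
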