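Package: refnet
Title: Multi-Omic Molecular Interaction Networks: Reconstruction, Knockout
    Damage and Growth Phenotype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building genome-scale multi-omic molecular interaction
    networks from database-export-like records using the reference-object
    approach (sequence-identity merging of genes, transcripts and proteins),
    for propagating gene-knockout damage through the network by Boolean
    fixed-point simulation, for constraint-based detection of blocked
    metabolic reactions and metabolites via gene-protein-reaction rules and
    flux-balance linear programming, for scoring the essentiality of
    molecular species and interactions against mutant growth phenotypes, and
    for predicting strain viability with a linear max-margin classifier under
    randomized hold-out validation. A synthetic-data module generates
    realistically structured networks and knockout studies with planted
    ground truth so the whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    methods,
    quadprog,
    seqinr,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
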