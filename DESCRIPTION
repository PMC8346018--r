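Package: screenlib
Title: Genetic-Algorithm Design of Target-Novelty-Optimized Screening Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing small-to-medium compound screening libraries.
    Curates a drug-like candidate pool from SMILES input (structure
    standardization, eligibility and property filters, structural alerts),
    predicts protein targets by Morgan-fingerprint Tanimoto similarity against
    a curated bioactivity reference set, scores the novelty of Pfam target
    families from dated bioactivity records, and selects an optimal N-compound
    subset with an elitist genetic algorithm maximizing a novelty-weighted,
    diversity-rewarding fitness function. Includes Taylor-Butina clustering,
    Murcko scaffold accounting and library characterization reports, plus
    deterministic synthetic data generators so the full pipeline can be
    exercised without external database downloads. Chemistry primitives
    (standardization, descriptors, fingerprints, scaffolds) are delegated to
    RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on the
    PATH (used only by the chemistry-backed functions).
Config/testthat/edition: 3
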