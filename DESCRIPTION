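Package: ppargmut
Title: Recurrent PPARgamma Mutation Calling, Activation Scoring and
    Structure Mapping in Bladder Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genomic analysis of recurrent activating
    PPARgamma mutations in luminal bladder tumors: harmonization of
    protein-level mutation calls across cohorts and isoform numbering
    frames, recurrence (hotspot) calling with optional pooling of
    external-database occurrences, lolliplot and oncoprint table
    generation, self-contained Fisher exact tests for co-occurrence and
    subgroup enrichment, a gene-expression-based PPARgamma activation
    score with quartile-contrast signature refinement, residue-level
    mapping of mutations onto protein structures (dimer interface and
    intra-chain contacts), seeded synthetic-data generators emulating
    tumor cohorts, and a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
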