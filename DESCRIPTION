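Package: DioxinScore
Title: Cross-Strain Scoring of Dioxin Transcriptional Responses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying hepatic transcriptional responses to
    2,3,7,8-tetrachlorodibenzo-p-dioxin (TCDD) across rat strains that are
    sensitive or resistant to dioxin toxicity. Implements per-strain
    empirical-Bayes moderated differential expression with
    Benjamini-Hochberg control, the tri-state (-1/0/+1) gene scoring scheme
    with collective sums that separates Type-I (concordant across all
    strains) from Type-II (collective-specific) responses, two-way overlap
    tables and proportion tests, permutation-based gene-category enrichment,
    correlation-distance hierarchical clustering, delta-delta-Ct qPCR
    quantification, and a synthetic-data generator emulating the
    four-strain, two-treatment, four-replicate design with known
    ground-truth gene classes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
biocViews: GeneExpression, DifferentialExpression, Microarray, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
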