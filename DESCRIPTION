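Package: phosphodiff
Title: Differential Phosphoproteomics for TMT Experiments and DIA Time
    Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantitative phosphoproteomics from
    search-engine output tables to biology-ready results. Reads
    evidence-style PSM tables with TMT reporter intensities and
    phospho-STY localization probabilities, applies
    decoy/contaminant/PEP confidence filters, normalizes phosphopeptide
    intensities by parent protein-group intensities, and tests for
    differential phosphorylation with a per-feature least-squares model,
    empirical-Bayes variance moderation and Benjamini-Hochberg
    correction. Aggregates site localization probabilities across PSMs,
    extracts phosphosite-centered sequence windows and computes scaled
    information-content motif matrices, performs hypergeometric
    over-representation analysis against GMT gene-set collections and
    ward.D2 hierarchical clustering of row-scaled intensity matrices.
    A separate branch handles DIA time-course protein matrices with
    q-value filtering, technical-replicate averaging, conservative
    minimum-replicate imputation with down-weighting, and weighted
    moderated differential testing with an effect-size threshold. A
    synthetic-data generator with full ground truth emulates the TMT
    6-plex (3 vs 3) and DIA time-course designs so every stage is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    fgsea,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
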