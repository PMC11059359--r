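Package: revscreen
Title: Signature-Reversal Drug Repurposing Screens from Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for transcriptome-based drug repurposing by
    signature reversal. From a two-group expression cohort (control vs disease)
    and a library of drug perturbation signatures, the package preprocesses the
    expression matrix (outlier winsorization, quantile normalization, gene
    standardization), selects differentially expressed genes by combined Welch t
    and Mann-Whitney tests with Benjamini-Hochberg control, and scores every drug
    for its ability to reverse the disease signature with three statistics: a
    Kolmogorov-Smirnov-style enrichment test (ET), a cosine similarity test (ST),
    and a Fisher-exact contingency test (CT) of oppositely-directed DEG overlaps.
    The three scores are combined by a normalized-rank ensemble, candidates are
    ranked per cohort and intersected across cohorts. A synthetic-data generator
    with recorded ground truth (planted DEGs, planted reverser and mimicker
    drugs, multi-cell-line profiles, RNA-seq-like counts) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
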