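Package: sciri
Title: Single-Cell Tumor and Immune Signatures of Immune Checkpoint Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking single-cell tumor and immune profiles of
    advanced non-small cell lung cancer biopsies to the response to immune checkpoint
    inhibitors. Implements quality control and normalization of UMI count matrices,
    antibody-derived-tag (ADT) assisted partitioning of T/NK cells into CD4+ T, CD8+ T
    and NK cells, expression-based copy-number inference with a standard-deviation /
    correlation rule and a mixture-model aneuploid caller for malignant-cell
    identification, tumor gene-program discovery (Wilcoxon differential expression with
    intersection/union signatures, rank-30 non-negative matrix factorization programs
    with Fisher odds-ratio enrichment, top-coefficient gene modules, principal-component
    signatures), TCR/BCR clonotype analysis with clone-size classes, the Ro/e
    observed-over-expected composition statistic, and a combinatorial tumor-plus-immune
    index screened by in-sample ROC AUC with Benjamini-Hochberg correction. A
    negative-binomial synthetic-cohort generator with planted ground truth makes every
    stage testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    nnet,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
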