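#!/usr/bin/env Rscript
# Quality control (mito < 20%, detected genes > 200, doublets out),
# log-normalization and highly-variable-gene selection.

library(sciri)

cohort <- read_cohort("results/cohort")
keep <- qc_filter(cohort)
metrics <- attr(keep, "metrics")
write.csv(metrics, "results/qc_report.csv", row.names = FALSE)

kept <- subset_cells(cohort, keep)
hvg <- select_hvg(kept$counts, n = min(2000, nrow(kept$counts)))
writeLines(hvg, "results/hvg.txt")

cat("kept", sum(keep), "of", length(keep), "cells;",
    "removed", sum(metrics$is_doublet), "doublets,",
    sum(!keep & !metrics$is_doublet), "low-quality cells\n")
cat("median detected genes:", median(metrics$n_genes_detected[keep]),
    " median mito fraction:", round(median(metrics$mito_fraction[keep]), 4), "\n")
cat("top variable genes written to results/hvg.txt\n")
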