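#!/usr/bin/env Rscript
# Generate the reference synthetic ICI cohort (14 RECIST samples, 5 PR / 3 SD
# / 6 PD, plus 2 normal-tissue samples) with planted ground truth, and write
# it to disk in 10x-style formats for the downstream stages.

library(sciri)

cfg <- sim_config(seed = 1)
sim <- simulate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort(sim$cohort, "results/cohort")

cm <- sim$cohort$cell_meta
cat("cells:", ncol(sim$cohort$counts), " genes:", nrow(sim$cohort$counts),
    " samples:", nrow(sim$cohort$sample_meta), "\n")
cat("planted malignant cells:", sum(sim$truth$cells$is_malignant), "\n")
cat("doublets:", sum(sim$truth$cells$is_doublet),
    " planted QC failures:", sum(sim$truth$cells$qc_fail), "\n")
print(table(cm$lineage))
cat("cohort written to results/cohort/\n")
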