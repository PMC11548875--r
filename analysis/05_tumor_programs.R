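#!/usr/bin/env Rscript
# Tumor gene signatures of the malignant cells: Wilcoxon DEGs for the three
# response comparisons with INT/UNION sets, rank-30 NMF programs with RECIST
# loading shares and Fisher odds-ratio enrichment, top-coefficient gene
# modules, and PC1-10 pos/neg signatures.

library(sciri)

cohort <- read_cohort("results/cohort")
keep <- qc_filter(cohort)
kept <- subset_cells(cohort, keep)
norm <- log_normalize(kept$counts)
cm <- kept$cell_meta
sm <- kept$sample_meta

cnv <- read.csv("results/cnv_summary.csv")
mal <- cm$barcode %in% cnv$barcode[cnv$consensus_call]
recist_of <- sm$recist[match(cm$sample_id, sm$sample_id)]

grp <- function(sel) cm$barcode[mal & sel]
deg <- list(
  responder_vs_nonresponder = wilcoxon_deg(norm, grp(recist_of %in% "PR"),
                                           grp(recist_of %in% c("SD", "PD"))),
  PR_vs_PD = wilcoxon_deg(norm, grp(recist_of %in% "PR"), grp(recist_of %in% "PD")),
  PR_vs_SD = wilcoxon_deg(norm, grp(recist_of %in% "PR"), grp(recist_of %in% "SD")))
for (nm in names(deg))
  write.csv(deg[[nm]]$table, sprintf("results/deg_%s.csv", nm), row.names = FALSE)
sigs <- build_int_union(deg)
cat("DEG set sizes:", paste(names(sigs),
    vapply(sigs, function(s) length(s$genes), numeric(1)), collapse = ", "), "\n")

model <- fit_nmf(as.matrix(kept$counts[, cm$barcode[mal]]), rank = 30, seed = 101)
recist_mal <- recist_of[mal]
programs <- derive_nmf_programs(model, recist_mal)
write.csv(data.frame(factor = rownames(programs$shares), programs$shares,
                     assignment = unname(programs$assignment)),
          "results/program_shares.csv", row.names = FALSE)
cat("NMF: final relative error", round(model$error, 4), ";",
    sum(!is.na(programs$assignment)), "of 30 factors RECIST-assigned\n")
sigs <- c(sigs, programs$programs)

cc <- cell_cycle_genes()
covs <- cbind(S = score_gene_set(norm, cc$S), G2M = score_gene_set(norm, cc$G2M))
hvg <- readLines("results/hvg.txt")
scaled_mal <- scale_and_regress(norm[hvg, cm$barcode[mal], drop = FALSE],
                                covs[cm$barcode[mal], ])
pcs <- pca_signatures(scaled_mal, n_pcs = 10, top_genes = 30)
sigs <- c(sigs, pcs$signatures)

jsonlite::write_json(
  lapply(sigs, function(s) list(genes = s$genes, direction = s$direction)),
  "results/signatures.json", auto_unbox = TRUE, pretty = TRUE)
cat("wrote", length(sigs), "signatures to results/signatures.json\n")
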