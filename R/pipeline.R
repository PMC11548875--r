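#' Default pipeline configuration
#'
#' Collects every stage's parameter block with defaults equal to the study
#' values: QC (mito < 20%, genes > 200), ADT gate (55th percentile), CNV
#' (cutoff 0.1, window 101, sd 0.03 / cor 0.3, epithelial reference < 20%),
#' DEG (0.25 / 0.01 / Bonferroni 0.01 / pct 0.25), NMF (rank 30, top 50
#' genes), modules (top 100), PCA signatures (10 PCs x 30 genes), clone bins
#' (1/5/10/20/Inf) and the ROC screen (6 top features paired).
#'
#' @param seed global random seed.
#' @param outdir artifact directory.
#' @param stages stages to run, in canonical order; subsets allowed.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L, outdir = "results/pipeline",
                                    stages = c("simulate", "qc", "gate", "cnv",
                                               "deg", "nmf", "pca", "repertoire",
                                               "roe", "classify"),
                                    sim = sim_config(seed = seed)) {
  sim$seed <- seed
  structure(list(
    seed = seed, outdir = outdir, stages = stages, sim = sim,
    qc = qc_thresholds(), gate = adt_gate_params(), cnv = cnv_params(),
    deg = deg_thresholds(),
    nmf = list(rank = 30, top_genes_per_factor = 50, margin = 0.25,
               max_iter = 100, tol = 1e-5),
    modules = list(top_n = 100),
    pca = list(n_pcs = 10, top_genes = 30, n_hvg = 2000),
    clone_bins = clone_size_bins(),
    screen = list(top_k = 6)), class = "pipeline_config")
}

log_line <- function(state, ...) {
  line <- paste0(...)
  cat(line, "\n", sep = "", file = state$logfile, append = TRUE)
  invisible(NULL)
}

write_tab <- function(df, state, name) {
  utils::write.csv(df, file.path(state$outdir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes (subsets of) simulate -> qc -> gate -> cnv -> deg -> nmf -> pca
#' -> repertoire -> roe -> classify in order, writing every intermediate
#' table as CSV under `config$outdir` and recording applied parameters in
#' `pipeline.log`. Identical config + seed gives byte-identical outputs.
#'
#' @param config a [default_pipeline_config()] (or path to a YAML file with
#'   overrides of its scalar fields).
#' @return list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$outdir <- config$outdir
  st$logfile <- file.path(config$outdir, "pipeline.log")
  cat("", file = st$logfile)
  log_line(st, "pipeline start; seed=", config$seed)
  canonical <- c("simulate", "qc", "gate", "cnv", "deg", "nmf", "pca",
                 "repertoire", "roe", "classify")
  stages <- intersect(canonical, config$stages)
  for (stage in stages) {
    fn <- get(paste0("stage_", stage), mode = "function")
    ok <- try(fn(st, config), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("pipeline stage '", stage, "' failed: ",
           attr(ok, "condition")$message)
    log_line(st, "stage ", stage, " done")
  }
  invisible(as.list(st))
}

#' Load a pipeline configuration from YAML
#'
#' Scalar overrides (seed, outdir, stages, and any named entries of the
#' stage parameter blocks) are applied on top of
#' [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = raw$seed %||% 1L)
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

stage_simulate <- function(st, config) {
  sim <- simulate_cohort(config$sim)
  st$cohort <- sim$cohort
  st$truth <- sim$truth
  log_line(st, "simulate: ", ncol(sim$cohort$counts), " cells, ",
           nrow(sim$cohort$counts), " genes, seed=", config$sim$seed)
  invisible(st)
}

stage_qc <- function(st, config) {
  keep <- qc_filter(st$cohort, config$qc)
  write_tab(attr(keep, "metrics"), st, "qc_report.csv")
  log_line(st, "qc: mito<", config$qc$mito_fraction_max, " genes>",
           config$qc$min_genes_detected, "; kept ", sum(keep), "/", length(keep))
  st$kept <- subset_cells(st$cohort, keep)
  st$truth_kept <- st$truth$cells[keep, , drop = FALSE]
  st$norm <- log_normalize(st$kept$counts)
  n_var <- sum(row_vars(as.matrix(st$kept$counts)) > 0)
  hvg <- select_hvg(st$kept$counts, n = min(config$pca$n_hvg, n_var))
  writeLines(hvg, file.path(st$outdir, "hvg.txt"))
  st$hvg <- hvg
  cc <- cell_cycle_genes()
  covs <- cbind(S = score_gene_set(st$norm, cc$S),
                G2M = score_gene_set(st$norm, cc$G2M))
  st$scaled <- scale_and_regress(st$norm, covs)
  invisible(st)
}

stage_gate <- function(st, config) {
  tnk <- st$kept$cell_meta$barcode[st$kept$cell_meta$lineage == "TNK"]
  # classifier feature space restricted to the top variable genes
  feat <- utils::head(st$hvg, 1000)
  st$tnk_labels <- classify_tnk(st$kept$counts, st$norm,
                                st$scaled[feat, , drop = FALSE],
                                st$kept$adt, tnk, config$gate)
  write_tab(st$tnk_labels, st, "tnk_labels.csv")
  amb <- mean(st$tnk_labels$label == "ambiguous")
  log_line(st, "gate: ADT percentile ", config$gate$adt_percentile,
           "; ambiguous fraction ", round(amb, 4))
  invisible(st)
}

stage_cnv <- function(st, config) {
  go <- build_genomic_order(st$kept$gene_positions,
                            rownames(st$kept$counts))
  cm <- st$kept$cell_meta
  sm <- st$kept$sample_meta
  normal_samples <- sm$sample_id[is.na(sm$recist)]
  tumor_samples <- setdiff(unique(cm$sample_id), normal_samples)
  # known-normal epithelium (normal-tissue samples) dilutes the reference
  normal_pool <- cm$barcode[cm$lineage == "Epithelial" &
                              cm$sample_id %in% normal_samples]
  st$cnv <- call_malignant_cells(st$norm, st$kept$counts, cm, go,
                                 config$cnv, normal_pool = normal_pool,
                                 tumor_samples = tumor_samples)
  write_tab(st$cnv, st, "cnv_summary.csv")
  st$malignant <- cm$barcode %in% st$cnv$barcode[st$cnv$consensus_call]
  log_line(st, "cnv: sd>", config$cnv$sd_threshold, " OR cor>",
           config$cnv$cor_threshold, "; malignant ", sum(st$malignant))
  invisible(st)
}

stage_deg <- function(st, config) {
  cm <- st$kept$cell_meta
  sm <- st$kept$sample_meta
  recist <- sm$recist[match(cm$sample_id, sm$sample_id)]
  mal <- st$malignant
  grp <- function(sel) cm$barcode[mal & sel]
  comparisons <- list(
    responder_vs_nonresponder = list(a = grp(recist %in% "PR"),
                                     b = grp(recist %in% c("SD", "PD"))),
    PR_vs_PD = list(a = grp(recist %in% "PR"), b = grp(recist %in% "PD")),
    PR_vs_SD = list(a = grp(recist %in% "PR"), b = grp(recist %in% "SD")))
  st$deg <- lapply(comparisons, function(cc)
    wilcoxon_deg(st$norm, cc$a, cc$b, config$deg))
  for (nm in names(st$deg))
    write_tab(st$deg[[nm]]$table, st, paste0("deg_", nm, ".csv"))
  st$signatures <- build_int_union(st$deg)
  log_line(st, "deg: |logFC|>", config$deg$min_abs_logfc, " p<",
           config$deg$max_p, " bonf<", config$deg$max_adj_p, " pct>=",
           config$deg$min_pct)
  invisible(st)
}

stage_nmf <- function(st, config) {
  cm <- st$kept$cell_meta
  sm <- st$kept$sample_meta
  mal_bc <- cm$barcode[st$malignant]
  v <- as.matrix(st$kept$counts[, mal_bc, drop = FALSE])
  st$nmf <- fit_nmf(v, rank = config$nmf$rank, max_iter = config$nmf$max_iter,
                    tol = config$nmf$tol, seed = config$seed + 101)
  recist <- sm$recist[match(cm$sample_id[st$malignant], sm$sample_id)]
  pr <- derive_nmf_programs(st$nmf, recist,
                            top_genes_per_factor = config$nmf$top_genes_per_factor,
                            margin = config$nmf$margin)
  st$nmf_programs <- pr
  utils::write.csv(round(st$nmf$W, 5), file.path(st$outdir, "nmf_W.csv"))
  utils::write.csv(round(st$nmf$H, 5), file.path(st$outdir, "nmf_H.csv"))
  shares <- data.frame(factor = rownames(pr$shares), pr$shares,
                       assignment = unname(pr$assignment), row.names = NULL)
  write_tab(shares, st, "program_shares.csv")
  st$signatures <- c(st$signatures, pr$programs)
  # top-coefficient module refinement on the assigned factors' loadings
  assigned <- pr$assignment[!is.na(pr$assignment)]
  if (length(assigned)) {
    coefs <- lapply(names(assigned), function(f) {
      w <- st$nmf$W[, f]; stats::setNames(as.numeric(w), rownames(st$nmf$W))
    })
    names(coefs) <- names(assigned)
    mods <- refine_top_gene_modules(coefs, assigned,
                                    top_n = config$modules$top_n)
    st$signatures <- c(st$signatures, mods)
  }
  # enrichment of program membership across RECIST groups
  if (length(pr$programs) >= 2) {
    sig_scores <- sapply(pr$programs, function(sg)
      colMeans(st$scaled[intersect(sg$genes, rownames(st$scaled)), mal_bc,
                         drop = FALSE]))
    assign_prog <- colnames(sig_scores)[max.col(sig_scores, ties.method = "first")]
    st$enrichment <- enrichment_odds_ratio(assign_prog, recist)
    write_tab(st$enrichment, st, "enrichment.csv")
  }
  log_line(st, "nmf: rank ", config$nmf$rank, ", final rel error ",
           round(st$nmf$error, 5))
  invisible(st)
}

stage_pca <- function(st, config) {
  mal_bc <- st$kept$cell_meta$barcode[st$malignant]
  hvg <- utils::head(st$hvg, config$pca$n_hvg)
  ps <- pca_signatures(st$scaled[hvg, mal_bc, drop = FALSE],
                       n_pcs = config$pca$n_pcs,
                       top_genes = config$pca$top_genes)
  st$pca <- ps
  st$signatures <- c(st$signatures, ps$signatures)
  sig_json <- lapply(st$signatures, function(sg)
    list(genes = sg$genes, direction = sg$direction,
         provenance = sg$provenance))
  jsonlite::write_json(sig_json, file.path(st$outdir, "signatures.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(st, "pca: ", config$pca$n_pcs, " PCs x ", config$pca$top_genes,
           " genes per sign")
  invisible(st)
}

stage_repertoire <- function(st, config) {
  cohort <- st$cohort
  kept_bc <- st$kept$cell_meta$barcode
  lab <- st$tnk_labels
  rows <- list()
  for (rec in c("TCR", "BCR")) {
    contigs <- attr(cohort, paste0("contigs_", tolower(rec)))
    if (is.null(contigs) || !nrow(contigs)) next
    contigs <- contigs[contigs$barcode %in% kept_bc, , drop = FALSE]
    ct <- call_clonotypes(contigs, rec)
    if (!nrow(ct)) next
    comp <- if (rec == "TCR") {
      lab$label[match(ct$barcode, lab$barcode)]
    } else rep("B", nrow(ct))
    samp <- st$kept$cell_meta$sample_id[match(ct$barcode, kept_bc)]
    keep <- !is.na(comp) & comp %in% c("CD4T", "CD8T", "B")
    ct <- classify_clone_sizes(ct[keep, , drop = FALSE], config$clone_bins,
                               compartment = comp[keep],
                               sample_ids = samp[keep])
    ct$receptor <- rec
    rows[[rec]] <- ct
  }
  st$clonotypes <- do.call(rbind, rows)
  rownames(st$clonotypes) <- NULL
  write_tab(st$clonotypes, st, "clonotypes.csv")
  fs <- functional_scores(st$norm)
  write_tab(fs, st, "functional_scores.csv")
  st$functional <- fs
  log_line(st, "repertoire: ", length(unique(st$clonotypes$clonotype_id)),
           " clonotypes over ", nrow(st$clonotypes), " paired cells")
  invisible(st)
}

stage_roe <- function(st, config) {
  cm <- st$kept$cell_meta
  sm <- st$kept$sample_meta
  core <- cm$sample_id %in% sm$sample_id[!is.na(sm$recist)]
  immune <- core & cm$lineage %in% c("TNK", "B", "Myeloid", "Mast")
  obs <- table(cm$subtype[immune], cm$sample_id[immune])
  st$roe <- compute_roe(unclass(obs))
  roe_df <- data.frame(subtype = rownames(st$roe$roe),
                       as.data.frame.matrix(st$roe$roe), check.names = FALSE)
  write_tab(roe_df, st, "roe_table.csv")
  resp <- sm$response[match(colnames(st$roe$roe), sm$sample_id)]
  props <- subtype_proportions(cm[core, , drop = FALSE], "immune")
  props <- props[, colnames(st$roe$roe), drop = FALSE]
  tests <- lapply(rownames(props), function(ty)
    compare_proportions(props[ty, ], resp))
  st$composition_tests <- data.frame(
    subtype = rownames(props),
    mean_difference = vapply(tests, `[[`, numeric(1), "mean_difference"),
    p = vapply(tests, `[[`, numeric(1), "p"), stringsAsFactors = FALSE)
  write_tab(st$composition_tests, st, "composition_tests.csv")
  log_line(st, "roe: ", nrow(props), " immune subtypes x ",
           ncol(props), " samples")
  invisible(st)
}

stage_classify <- function(st, config) {
  sm <- st$kept$sample_meta
  sm <- sm[!is.na(sm$recist), , drop = FALSE]
  samples <- sm$sample_id
  response01 <- as.integer(sm$response == "non_responder")
  # immune features: Ro/e per subtype
  fm <- t(st$roe$roe[, samples, drop = FALSE])
  colnames(fm) <- paste0("Roe.", colnames(fm))
  # tumor features: max-normalized per-sample signature scores
  cm <- st$kept$cell_meta
  tumor_sigs <- st$signatures
  scores <- sapply(tumor_sigs, function(sg) {
    if (!length(sg$genes)) return(rep(NA_real_, length(samples)))
    sc <- score_signature_per_sample(st$norm, sg, st$malignant, cm$sample_id)
    sc[samples]
  })
  rownames(scores) <- samples
  ok <- colSums(is.na(scores)) == 0 & apply(scores, 2, stats::sd) > 0
  fm <- cbind(fm, scores[, ok, drop = FALSE])
  st$feature_matrix <- fm
  uni <- lapply(colnames(fm), function(f)
    univariate_regression(fm[, f], response01))
  st$univariate <- data.frame(
    feature = colnames(fm),
    coefficient = vapply(uni, `[[`, numeric(1), "coefficient"),
    p = vapply(uni, `[[`, numeric(1), "p"), stringsAsFactors = FALSE)
  # clinical covariates screened alongside
  for (cv in c("tissue_origin", "subtype", "stage", "smoking")) {
    u <- univariate_regression(sm[[cv]], response01)
    st$univariate <- rbind(st$univariate,
                           data.frame(feature = paste0("clinical.", cv),
                                      coefficient = u$coefficient, p = u$p))
  }
  write_tab(st$univariate, st, "univariate.csv")
  write_tab(data.frame(sample_id = samples, fm, check.names = FALSE),
            st, "sample_signature_scores.csv")
  st$roc_screen <- screen_combinations(fm, response01, top_k = config$screen$top_k)
  write_tab(st$roc_screen, st, "roc_screen.csv")
  best <- st$roc_screen[1, ]
  best_pair <- st$roc_screen[st$roc_screen$type == "pair", ][1, ]
  report <- c(
    "# Response classification report", "",
    paste0("Samples: ", length(samples), " (",
           sum(response01 == 0), " responders / ", sum(response01 == 1),
           " non-responders)"),
    paste0("Features screened: ", ncol(fm), " (+", 4, " clinical)"),
    paste0("Best combination: ", best$name, " (", best$type, ") AUC = ",
           round(best$auc, 4), ", q = ", round(best$q, 4)),
    paste0("Best pair index: ", best_pair$name, " AUC = ",
           round(best_pair$auc, 4), ", q = ", round(best_pair$q, 4)), "",
    "Top 10 combinations:", "",
    utils::capture.output(print(utils::head(
      st$roc_screen[, c("name", "type", "auc", "p", "q")], 10),
      row.names = FALSE)))
  writeLines(report, file.path(st$outdir, "classifier_report.md"))
  log_line(st, "classify: best ", best$name, " auc=", round(best$auc, 4))
  invisible(st)
}
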