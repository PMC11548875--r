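#' Configuration for the synthetic-cohort generator
#'
#' The defaults define the reference study conditions used throughout the
#' package's tests: 14 pre-treatment samples (5 PR, 3 SD, 6 PD, mirroring the
#' cohort table of the motivating study), 600 cells per sample, a 2,000-gene
#' synthetic genome on six chromosomes, negative-binomial UMI counts around
#' lineage-specific gene programs, genome-wide arm-scale CNV in malignant
#' cells, a RECIST-dependent tumor gene program, ADT counts separating
#' CD4/CD8/NK, composition shifts by response group (Treg/TRM/TH17 enriched in
#' non-responders, CD8 TEM in responders) and clonally expanded TCR/BCR
#' repertoires. See the methods vignette for the rationale behind each value.
#'
#' @param n_samples number of samples.
#' @param samples_per_group named counts of PR/SD/PD samples (must sum to
#'   `n_samples`).
#' @param cells_per_sample cells drawn per sample (before doublets).
#' @param n_normal_samples normal-tissue samples (nLung/nLN-like: immune +
#'   normal epithelium, no malignant cells, no RECIST); their epithelial
#'   cells serve as the known-normal spike-in pool for CNV reference
#'   dilution.
#' @param n_genes genes in the synthetic genome (>= 150).
#' @param composition_effects list with `responder` / `non_responder` named
#'   numeric vectors of per-subtype log-odds shifts. `NULL` disables all
#'   shifts (null cohort).
#' @param tumor_program_panel named list (keys among PR/SD/PD/responder/
#'   non_responder) of `list(frac=, fold=)` or `list(genes=, fold=)` tumor
#'   gene programs applied to malignant cells of matching samples.
#' @param cnv_events list of CNV events (`chromosome`, `start_gene_index`
#'   global genome-order index, `n_genes`, `fold_change`); default:
#'   [default_cnv_events()]. Empty list disables malignancy.
#' @param nb_dispersion gene-level negative-binomial dispersion (1/size).
#' @param library_size list(meanlog, sdlog) of the per-cell lognormal library
#'   size.
#' @param adt_separation list(pos_mean, neg_mean, size, depth_sdlog).
#' @param clonal_expansion list(alpha = named power-law exponents per subtype
#'   with a `default`, max_clone).
#' @param doublet_rate fraction of additional cells built by summing two
#'   random cells' counts.
#' @param low_quality_rate fraction of cells with mitochondrial overload
#'   (planted QC failures).
#' @param dirichlet_concentration concentration of the per-sample Dirichlet
#'   over subtype proportions.
#' @param mito_mass baseline fraction of counts from mitochondrial genes.
#' @param cycling_rate,cycling_mult fraction of cycling cells and the
#'   multiplier on cell-cycle genes in them.
#' @param marker_on_mult weight multiplier of marker genes in expressing
#'   subtypes (relative to the baseline gene weight scale).
#' @param marker_off_count expected per-cell count of a marker gene in
#'   non-expressing subtypes (fixed in count space so that marker leakage
#'   does not depend on genome size or sequencing depth).
#' @param program_base_mult baseline weight multiplier for tumor-program
#'   genes (keeps them well expressed in all cells).
#' @param base_weight_sdlog lognormal sd of baseline gene weights.
#' @param seed RNG seed for [simulate_cohort()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 14,
                       samples_per_group = c(PR = 5, SD = 3, PD = 6),
                       cells_per_sample = 600,
                       n_normal_samples = 2,
                       n_genes = 2000,
                       composition_effects = list(
                         responder = c(CD8_TEM = 0.7),
                         non_responder = c(CD4_Treg = 0.7, CD4_TRM = 0.7,
                                           CD4_TH17 = 0.7)),
                       tumor_program_panel = list(
                         non_responder = list(frac = 0.04, fold = 1.6)),
                       cnv_events = NULL,
                       nb_dispersion = 0.012,
                       library_size = list(meanlog = log(55000), sdlog = 0.15),
                       adt_separation = list(pos_mean = 150, neg_mean = 8,
                                             size = 6, depth_sdlog = 0.4),
                       clonal_expansion = list(
                         alpha = c(default = 3, CD8_TEM = 2, CD8_TEX = 1.3, B = 2.5),
                         max_clone = 40),
                       doublet_rate = 0.03,
                       low_quality_rate = 0.05,
                       dirichlet_concentration = 80,
                       mito_mass = 0.05,
                       cycling_rate = 0.05,
                       cycling_mult = 4,
                       marker_on_mult = 1.5,
                       marker_off_count = 0.01,
                       program_base_mult = 2,
                       base_weight_sdlog = 0.3,
                       seed = 1L) {
  if (sum(samples_per_group) != n_samples)
    stop("samples_per_group must sum to n_samples")
  if (is.null(cnv_events)) cnv_events <- default_cnv_events(n_genes)
  if (!is.null(composition_effects)) {
    shifts <- unlist(composition_effects)
    if (length(shifts) && any(!is.finite(shifts)))
      stop("composition log-odds shifts must be finite")
  }
  for (pg in tumor_program_panel)
    if (!is.null(pg$fold) && pg$fold <= 0) stop("program fold changes must be > 0")
  structure(as.list(environment()), class = "sim_config")
}

sim_config_to_list <- function(cfg) lapply(unclass(cfg), function(x) x)

# Baseline subtype composition and coarse-lineage map of the synthetic cohort.
subtype_table <- function() {
  data.frame(
    subtype = c("Epithelial_normal", "Malignant", "CD4_TN", "CD4_Treg",
                "CD4_TRM", "CD4_TH17", "CD8_TEM", "CD8_TEX", "CD8_TN",
                "NK", "B", "Myeloid", "Mast"),
    lineage = c("Epithelial", "Epithelial", rep("TNK", 8), "B", "Myeloid", "Mast"),
    prop = c(0.05, 0.20, 0.08, 0.06, 0.06, 0.03, 0.12, 0.08, 0.06,
             0.07, 0.09, 0.08, 0.02),
    stringsAsFactors = FALSE)
}

#' Synthetic genome and marker panel
#'
#' Builds the gene universe: named marker/mitochondrial/cell-cycle genes are
#' scattered uniformly along the genome in a fixed shuffled order (clustered
#' lineage markers would mimic CNV blocks after window smoothing), with
#' filler genes in between. Six chromosomes sized 20/18/17/16/15/14% of the
#' genome so that arm-scale contiguous CNV events fit on single chromosomes.
#'
#' @param n_genes total genes (>= 150).
#' @return list with `genes`, `gene_positions`, `marker_sets`, `mito_genes`,
#'   `cc_genes`, `chromosomes` and helper indices.
#' @export
default_gene_panel <- function(n_genes = 2000) {
  mito <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
                          "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"))
  marker_sets <- list(
    T_pan      = c("CD3D", "CD3E", "CD3G", "CD2", "TRAC"),
    CD4_pan    = c("CD4", "IL7R"),
    CD8_pan    = c("CD8A", "CD8B"),
    naive      = c("SELL", "TCF7", "LEF1", "CCR7"),
    regulatory = c("ICOS", "FOXP3", "IKZF2", "LAYN", "TNFRSF18", "CTLA4",
                   "IL21R", "BATF", "CCR8", "IL2RA", "TNFRSF4"),
    trm        = c("NR4A1", "MYADM", "PTGER4", "ITGA1"),
    th17       = c("RORC", "IL17A", "CCR6", "KLRB1"),
    tem        = c("GZMK", "CXCR4", "IFNG"),
    tex        = c("HAVCR2", "PDCD1", "LAG3", "TIGIT", "CXCL13"),
    cytotoxic  = c("CX3CR1", "PRF1", "GZMA", "GZMB", "GZMH", "GNLY",
                   "KLRG1", "NKG7"),
    nk         = c("XCL1", "NCAM1", "KLRD1", "KLRF1"),
    b          = c("CD79A", "CD79B", "MS4A1", "CD19"),
    myeloid    = c("LYZ", "CD68", "CD14", "AIF1", "C1QA"),
    mast       = c("TPSAB1", "TPSB2", "CPA3", "MS4A2"),
    epithelial = c("EPCAM", "KRT18", "KRT19", "KRT8", "NAPSA"))
  cc_genes <- list(
    S   = c("MCM5", "PCNA", "TYMS", "FEN1", "MCM2", "MCM4", "RRM1", "UNG",
            "GINS2", "MCM6", "CDCA7", "DTL"),
    G2M = c("HMGB2", "CDK1", "NUSAP1", "UBE2C", "BIRC5", "TPX2", "TOP2A",
            "NDC80", "CKS2", "NUF2", "CKS1B", "MKI67"))
  special <- c(mito, unique(unlist(marker_sets)), unlist(cc_genes))
  if (n_genes < length(special) + 40)
    stop("n_genes too small for the marker panel (need >= ", length(special) + 40, ")")
  filler <- sprintf("G%04d", seq_len(n_genes - length(special)))
  # scatter the named genes evenly along the genome in a fixed shuffled order:
  # lineage-specific marker expression must not form genomically contiguous
  # blocks, which would mimic CNV in the window-smoothed signal
  special <- with_seed(760351, sample(special))
  special_pos <- round(seq(2, n_genes - 1, length.out = length(special)))
  genes <- character(n_genes)
  genes[special_pos] <- special
  genes[genes == ""] <- filler
  chromosomes <- paste0("chr", 1:6)
  sizes <- floor(n_genes * c(0.20, 0.18, 0.17, 0.16, 0.15, 0.14))
  sizes[6] <- n_genes - sum(sizes[1:5])
  chrom <- rep(chromosomes, times = sizes)
  within <- unlist(lapply(sizes, seq_len))
  gene_positions <- data.frame(
    gene_id = genes, chromosome = chrom,
    start = (within - 1) * 100000 + 1,
    end = (within - 1) * 100000 + 1000,
    stringsAsFactors = FALSE)
  list(genes = genes, gene_positions = gene_positions,
       marker_sets = marker_sets, mito_genes = mito, cc_genes = cc_genes,
       chromosomes = chromosomes, chrom_sizes = stats::setNames(sizes, chromosomes),
       is_filler = startsWith(genes, "G"), n_filler = length(filler))
}

#' Default arm-scale CNV events of the synthetic malignant genome
#'
#' Genome-wide aneuploidy: three gains and two losses covering ~55% of genes,
#' including one >= 300-gene x1.5 gain on chromosome 1 (at the default 2,000
#' genes). Event coordinates scale with `n_genes`.
#'
#' @param n_genes genome size.
#' @return list of events (`chromosome`, `start_gene_index` in global genome
#'   order, `n_genes`, `fold_change`).
#' @export
default_cnv_events <- function(n_genes = 2000) {
  sizes <- floor(n_genes * c(0.20, 0.18, 0.17, 0.16, 0.15, 0.14))
  sizes[6] <- n_genes - sum(sizes[1:5])
  offset <- cumsum(c(0, sizes))
  ev <- function(chr, at_frac, len_frac, fold) {
    list(chromosome = paste0("chr", chr),
         start_gene_index = offset[chr] + max(1L, floor(sizes[chr] * at_frac)),
         n_genes = max(2L, floor(n_genes * len_frac)),
         fold_change = fold)
  }
  list(ev(1, 0.12, 0.150, 1.5),
       ev(2, 0.25, 0.125, 0.65),
       ev(4, 0.18, 0.100, 1.4),
       ev(5, 0.15, 0.100, 0.7),
       ev(6, 0.15, 0.075, 1.5))
}

#' Apply CNV events to per-gene expected means
#'
#' Multiplies the expected mean of each event gene by the event fold change,
#' for malignant lineages only. Events must reference contiguous gene runs on
#' a single chromosome and must not overlap.
#'
#' @param base_means genes x lineage matrix of expected means (rownames =
#'   gene ids in genomic order).
#' @param events list of events as in [default_cnv_events()].
#' @param gene_positions genomic position table aligned with `base_means`
#'   rows.
#' @param malignant_lineages column names of `base_means` to modify.
#' @return matrix of the same shape with event genes scaled in malignant
#'   columns.
#' @export
plant_cnv_events <- function(base_means, events, gene_positions,
                             malignant_lineages = "Malignant") {
  if (!length(events)) return(base_means)
  n <- nrow(base_means)
  touched <- integer(0)
  for (ev in events) {
    idx <- seq(ev$start_gene_index, length.out = ev$n_genes)
    if (max(idx) > n) stop("event gene index out of range")
    chr <- gene_positions$chromosome[idx]
    if (!all(chr == ev$chromosome))
      stop("event ", ev$chromosome, " crosses a chromosome boundary")
    if (any(idx %in% touched)) stop("overlapping CNV events on the same genes")
    touched <- c(touched, idx)
    for (ml in malignant_lineages)
      base_means[idx, ml] <- base_means[idx, ml] * ev$fold_change
  }
  base_means
}

# Resolve a tumor-program panel entry to explicit filler genes on chr3
# (a chromosome free of default CNV events), consecutive non-overlapping
# slices for multiple programs; named marker genes are skipped so programs
# never confound lineage scoring.
resolve_program_genes <- function(panel, gene_panel, n_genes) {
  if (!length(panel)) return(list())
  gp <- gene_panel$gene_positions
  candidates <- gene_panel$genes[gp$chromosome == "chr3" & gene_panel$is_filler]
  cursor <- max(1L, floor(length(candidates) * 0.1))
  out <- list()
  for (nm in names(panel)) {
    pg <- panel[[nm]]
    if (!is.null(pg$genes)) {
      gene_ids <- pg$genes
      if (!all(gene_ids %in% gene_panel$genes))
        stop("unknown program gene in panel '", nm, "'")
    } else {
      k <- max(5L, round(n_genes * (pg$frac %||% 0.04)))
      if (cursor + k - 1L > length(candidates))
        stop("tumor program '", nm, "' does not fit on chr3; shrink frac or grow n_genes")
      gene_ids <- candidates[seq(cursor, length.out = k)]
      cursor <- cursor + k
    }
    out[[nm]] <- list(genes = gene_ids, fold = pg$fold %||% 1.6)
  }
  out
}

# Does a program panel key apply to a RECIST group?
program_applies <- function(key, recist) {
  switch(key,
         responder = recist == "PR",
         non_responder = recist %in% c("SD", "PD"),
         key == recist)
}

#' Simulate a synthetic ICI cohort with ground truth
#'
#' Draws UMI counts negative-binomially around subtype-specific gene
#' programs scaled by lognormal library sizes; subtype proportions per sample
#' come from a Dirichlet whose mean is shifted on the log scale by the
#' response group's composition effects; malignant cells carry the CNV events
#' and their sample's RECIST tumor program; ADT counts separate CD4/CD8/NK;
#' doublets are created by summing two random cells; a small fraction of
#' cells gets mitochondrial overload (planted QC failures). Paired TCR/BCR
#' contigs with planted clonal structure are attached.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a `cell_cohort` with `truth`, `contigs_tcr`,
#'   `contigs_bcr`, `sim_config` attributes) and `truth` (list: `cells`
#'   per-cell truth table, `genes` per-gene program membership, `events`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    panel <- default_gene_panel(config$n_genes)
    genes <- panel$genes
    n_genes <- config$n_genes
    st <- subtype_table()
    have_cnv <- length(config$cnv_events) > 0
    if (!have_cnv) {
      # without planted CNV there is no observable malignancy: merge the
      # malignant compartment into normal epithelium
      st$prop[st$subtype == "Epithelial_normal"] <-
        st$prop[st$subtype == "Epithelial_normal"] + st$prop[st$subtype == "Malignant"]
      st <- st[st$subtype != "Malignant", ]
    }

    ## ---- per-subtype expression weights -------------------------------
    base_w <- stats::rlnorm(n_genes, 0, config$base_weight_sdlog)
    names(base_w) <- genes
    marker_genes <- unique(unlist(panel$marker_sets))
    non_marker_sum <- sum(base_w[setdiff(genes, marker_genes)])
    base_w[marker_genes] <- config$marker_off_count * non_marker_sum /
      exp(config$library_size$meanlog)
    base_w[unlist(panel$cc_genes)] <- 0.08
    programs <- resolve_program_genes(config$tumor_program_panel, panel, n_genes)
    for (pg in programs) base_w[pg$genes] <- base_w[pg$genes] * config$program_base_mult
    # fix baseline mitochondrial mass fraction
    mito_idx <- match(panel$mito_genes, genes)
    non_mito_sum <- sum(base_w[-mito_idx])
    base_w[mito_idx] <- config$mito_mass / (1 - config$mito_mass) *
      non_mito_sum / length(mito_idx)

    on_map <- list(
      T_pan = c("CD4_TN", "CD4_Treg", "CD4_TRM", "CD4_TH17",
                "CD8_TEM", "CD8_TEX", "CD8_TN"),
      CD4_pan = c("CD4_TN", "CD4_Treg", "CD4_TRM", "CD4_TH17"),
      CD8_pan = c("CD8_TEM", "CD8_TEX", "CD8_TN"),
      naive = c("CD4_TN", "CD8_TN"),
      regulatory = "CD4_Treg", trm = "CD4_TRM", th17 = "CD4_TH17",
      tem = "CD8_TEM", tex = "CD8_TEX",
      cytotoxic = c("CD8_TEM", "CD8_TEX", "NK"),
      nk = "NK", b = "B", myeloid = "Myeloid", mast = "Mast",
      epithelial = c("Epithelial_normal", "Malignant"))
    W <- matrix(base_w, n_genes, nrow(st), dimnames = list(genes, st$subtype))
    for (set_name in names(panel$marker_sets)) {
      on_in <- intersect(on_map[[set_name]], st$subtype)
      if (length(on_in))
        W[panel$marker_sets[[set_name]], on_in] <- config$marker_on_mult
    }
    if (have_cnv && "Malignant" %in% colnames(W))
      W <- plant_cnv_events(W, config$cnv_events, panel$gene_positions,
                            malignant_lineages = "Malignant")
    # expand malignant column into per-RECIST variants carrying the tumor program
    recist_levels <- c("PR", "SD", "PD")
    if ("Malignant" %in% colnames(W)) {
      for (rl in recist_levels) {
        col <- W[, "Malignant"]
        for (nm in names(programs)) {
          if (program_applies(nm, rl)) {
            pg <- programs[[nm]]
            col[pg$genes] <- col[pg$genes] * pg$fold
          }
        }
        W <- cbind(W, col)
        colnames(W)[ncol(W)] <- paste0("Malignant.", rl)
      }
    }

    ## ---- samples and composition --------------------------------------
    recist <- rep(names(config$samples_per_group), times = config$samples_per_group)
    n_core <- config$n_samples
    n_norm <- config$n_normal_samples %||% 0
    n_samples <- n_core + n_norm
    sample_ids <- c(sprintf("S%02d", seq_len(n_core)),
                    if (n_norm) sprintf("N%02d", seq_len(n_norm)))
    recist <- c(recist, rep(NA_character_, n_norm))
    response <- ifelse(is.na(recist), NA_character_,
                       ifelse(recist == "PR", "responder", "non_responder"))
    # a few patients contribute two samples (mirrors the source cohort table)
    patient <- seq_len(n_core)
    if (n_core >= 10 && identical(unname(config$samples_per_group), c(5L, 3L, 6L)))
      patient <- c(1, 1, 2, 3, 4, 5, 5, 6, 7, 7, 8, 9, 10, 11)
    patient <- c(patient, if (n_norm) max(patient) + seq_len(n_norm))
    sample_meta <- data.frame(
      sample_id = sample_ids,
      patient_id = sprintf("P%02d", patient),
      recist = recist, response = response,
      tissue_origin = c(rep(c("mLN", "Lung", "PE", "mLN", "Liver"),
                            length.out = n_core),
                        rep(c("nLung", "nLN"), length.out = n_norm)),
      subtype = c(rep(c("AD", "AD", "SQ", "AD", "AD"), length.out = n_core),
                  rep(NA_character_, n_norm)),
      stage = c(rep("IV", n_core), rep(NA_character_, n_norm)),
      smoking = rep(c("ever", "never"), length.out = n_samples),
      stringsAsFactors = FALSE)

    shift_for <- function(resp) {
      s <- stats::setNames(rep(0, nrow(st)), st$subtype)
      if (!is.null(config$composition_effects) && !is.na(resp)) {
        eff <- config$composition_effects[[resp]]
        if (!is.null(eff)) {
          keep <- intersect(names(eff), names(s))
          s[keep] <- eff[keep]
        }
      }
      s
    }

    cell_subtype <- character(0); cell_sample <- character(0)
    for (i in seq_len(n_samples)) {
      p <- st$prop * exp(shift_for(response[i]))
      if (is.na(recist[i]) && "Malignant" %in% st$subtype) {
        # normal tissue: epithelium present, malignancy absent
        p[st$subtype == "Epithelial_normal"] <-
          p[st$subtype == "Epithelial_normal"] + p[st$subtype == "Malignant"]
        p[st$subtype == "Malignant"] <- 0
      }
      p <- p / sum(p)
      props <- rdirichlet1(config$dirichlet_concentration * p)
      k <- as.vector(stats::rmultinom(1, config$cells_per_sample, props))
      cell_subtype <- c(cell_subtype, rep(st$subtype, times = k))
      cell_sample <- c(cell_sample, rep(sample_ids[i], times = sum(k)))
    }
    n_cells <- length(cell_subtype)
    barcode <- sprintf("%s_C%04d", cell_sample, stats::ave(
      seq_len(n_cells), cell_sample, FUN = seq_along))

    ## ---- counts ---------------------------------------------------------
    wcol <- cell_subtype
    mal <- cell_subtype == "Malignant"
    wcol[mal] <- paste0("Malignant.",
                        sample_meta$recist[match(cell_sample[mal], sample_ids)])
    M <- W[, wcol, drop = FALSE]
    low_q <- stats::runif(n_cells) < config$low_quality_rate
    if (any(low_q)) M[mito_idx, low_q] <- M[mito_idx, low_q] * 10
    cycling <- stats::runif(n_cells) < config$cycling_rate
    cc_idx <- match(unlist(panel$cc_genes), genes)
    if (any(cycling)) M[cc_idx, cycling] <- M[cc_idx, cycling] * config$cycling_mult
    lib <- stats::rlnorm(n_cells, config$library_size$meanlog,
                         config$library_size$sdlog)
    M <- sweep(M, 2, colSums(M), "/")
    M <- sweep(M, 2, lib, "*")
    counts <- matrix(stats::rnbinom(length(M), mu = as.vector(M),
                                    size = 1 / config$nb_dispersion),
                     n_genes, n_cells, dimnames = list(genes, barcode))
    rm(M)

    ## ---- ADT ------------------------------------------------------------
    adt_markers <- c("CD4", "CD8", "CD45", "CD56")
    as_ <- config$adt_separation
    adt_mu <- matrix(as_$neg_mean, 4, n_cells, dimnames = list(adt_markers, barcode))
    lin <- st$lineage[match(cell_subtype, st$subtype)]
    adt_mu["CD4", grepl("^CD4_", cell_subtype)] <- as_$pos_mean
    adt_mu["CD8", grepl("^CD8_", cell_subtype)] <- as_$pos_mean
    adt_mu["CD45", lin != "Epithelial"] <- as_$pos_mean * 1.3
    adt_mu["CD56", cell_subtype == "NK"] <- as_$pos_mean
    depth <- stats::rlnorm(n_cells, 0, as_$depth_sdlog)
    adt_mu <- sweep(adt_mu, 2, depth, "*")
    adt <- matrix(stats::rnbinom(length(adt_mu), mu = as.vector(adt_mu),
                                 size = as_$size),
                  4, n_cells, dimnames = dimnames(adt_mu))

    ## ---- doublets -------------------------------------------------------
    n_doub <- round(config$doublet_rate * n_cells)
    if (n_doub > 0) {
      a <- sample.int(n_cells, n_doub, replace = TRUE)
      b <- sample.int(n_cells, n_doub, replace = TRUE)
      dc <- counts[, a, drop = FALSE] + counts[, b, drop = FALSE]
      da <- adt[, a, drop = FALSE] + adt[, b, drop = FALSE]
      dbar <- sprintf("%s_D%04d", cell_sample[a], seq_len(n_doub))
      colnames(dc) <- dbar; colnames(da) <- dbar
      counts <- cbind(counts, dc); adt <- cbind(adt, da)
      cell_subtype <- c(cell_subtype, cell_subtype[a])
      cell_sample <- c(cell_sample, cell_sample[a])
      lib <- c(lib, lib[a] + lib[b])
      low_q <- c(low_q, low_q[a] | low_q[b])
      cycling <- c(cycling, rep(FALSE, n_doub))
      mal <- c(mal, rep(FALSE, n_doub))
      barcode <- c(barcode, dbar)
      is_doublet <- c(rep(FALSE, n_cells), rep(TRUE, n_doub))
      n_cells <- n_cells + n_doub
    } else is_doublet <- rep(FALSE, n_cells)

    lineage <- st$lineage[match(cell_subtype, st$subtype)]
    truth_cells <- data.frame(
      barcode = barcode, sample_id = cell_sample,
      subtype = cell_subtype, lineage = lineage,
      is_malignant = cell_subtype == "Malignant" & have_cnv & !is_doublet,
      is_doublet = is_doublet, qc_fail = low_q, is_cycling = cycling,
      library_size = lib,
      clonotype_id = NA_character_, stringsAsFactors = FALSE)

    ## ---- repertoires ----------------------------------------------------
    contigs_tcr <- simulate_repertoire(truth_cells, config$clonal_expansion,
                                       receptor = "TCR")
    contigs_bcr <- simulate_repertoire(truth_cells, config$clonal_expansion,
                                       receptor = "BCR")
    for (tab in list(contigs_tcr, contigs_bcr)) {
      ids <- attr(tab, "clonotype_truth")
      if (!is.null(ids))
        truth_cells$clonotype_id[match(names(ids), truth_cells$barcode)] <- ids
    }

    cell_meta <- data.frame(
      barcode = barcode, sample_id = cell_sample,
      patient_id = sample_meta$patient_id[match(cell_sample, sample_ids)],
      lineage = lineage, subtype = cell_subtype,
      is_doublet = is_doublet, stringsAsFactors = FALSE)

    truth <- list(cells = truth_cells,
                  genes = program_membership(programs),
                  events = config$cnv_events)
    cohort <- cell_cohort(counts, cell_meta, sample_meta, adt = adt,
                          gene_positions = panel$gene_positions)
    attr(cohort, "truth") <- truth
    attr(cohort, "contigs_tcr") <- contigs_tcr
    attr(cohort, "contigs_bcr") <- contigs_bcr
    attr(cohort, "sim_config") <- config
    list(cohort = cohort, truth = truth)
  })
}

program_membership <- function(programs) {
  if (!length(programs))
    return(data.frame(gene_id = character(0), program = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(names(programs), function(nm)
    data.frame(gene_id = programs[[nm]]$genes, program = nm,
               stringsAsFactors = FALSE)))
}

#' Simulate paired-chain TCR or BCR contigs with planted clones
#'
#' Every T cell receives one TRA+TRB pair (B cells one IGH + IGK/IGL pair);
#' cells of the same clonotype share V(D)JC genes and the CDR3 nucleotide
#' sequence. Clone sizes follow a truncated power law `P(s) ~ s^-alpha`
#' within each (sample, subtype) pool, with subtype-specific exponents
#' (heavier tail for exhausted CD8 T cells).
#'
#' @param t_cell_truth per-cell truth table (`barcode`, `sample_id`,
#'   `subtype`, `is_doublet`).
#' @param clonal_expansion list(alpha = named exponents with `default`,
#'   max_clone).
#' @param receptor "TCR" (CD4/CD8 subtypes) or "BCR" (B cells).
#' @return contig data.frame (barcode, chain, v_gene, d_gene, j_gene,
#'   c_gene, cdr3_nt, umis) with a `clonotype_truth` attribute (named vector
#'   barcode -> planted clonotype id).
#' @export
simulate_repertoire <- function(t_cell_truth, clonal_expansion,
                                receptor = c("TCR", "BCR")) {
  receptor <- match.arg(receptor)
  tc <- t_cell_truth[!t_cell_truth$is_doublet, , drop = FALSE]
  tc <- if (receptor == "TCR") {
    tc[grepl("^CD[48]_", tc$subtype), , drop = FALSE]
  } else tc[tc$subtype == "B", , drop = FALSE]
  alpha_of <- function(subtype) {
    a <- clonal_expansion$alpha
    if (subtype %in% names(a)) a[[subtype]] else a[["default"]]
  }
  smax <- clonal_expansion$max_clone %||% 40
  # pass 1: partition every pool's cells into clones (vectors only)
  cell_bc <- character(0); cell_clone <- integer(0); clone_sizes <- integer(0)
  clone_counter <- 0L
  pools <- split(tc$barcode, list(tc$sample_id, tc$subtype), drop = TRUE)
  for (pool_name in names(pools)) {
    bcs <- sample(pools[[pool_name]])
    subtype <- sub("^[^.]*\\.", "", pool_name)
    alpha <- alpha_of(subtype)
    pr <- (1:smax)^(-alpha); pr <- pr / sum(pr)
    n <- length(bcs)
    # draw plenty of clone sizes at once, then trim to the pool size
    draws <- sample.int(smax, n, replace = TRUE, prob = pr)
    csum <- cumsum(draws)
    k <- which(csum >= n)[1]
    draws <- draws[seq_len(k)]
    draws[k] <- draws[k] - (csum[k] - n)
    cell_bc <- c(cell_bc, bcs)
    cell_clone <- c(cell_clone, rep(clone_counter + seq_along(draws), draws))
    clone_sizes <- c(clone_sizes, draws)
    clone_counter <- clone_counter + length(draws)
  }
  # pass 2: one set of chain genes per clone, expanded to cells
  n_clones <- clone_counter
  chain_tabs <- clone_chain_table(receptor, n_clones)
  out_list <- lapply(chain_tabs, function(ch) {
    idx <- cell_clone
    data.frame(barcode = cell_bc, chain = ch$chain[idx], v_gene = ch$v[idx],
               d_gene = ch$d[idx], j_gene = ch$j[idx], c_gene = ch$c[idx],
               cdr3_nt = ch$cdr3[idx],
               umis = stats::rpois(length(idx), 4) + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out_list)
  if (is.null(out))
    out <- data.frame(barcode = character(0), chain = character(0),
                      v_gene = character(0), d_gene = character(0),
                      j_gene = character(0), c_gene = character(0),
                      cdr3_nt = character(0), umis = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "clonotype_truth") <-
    stats::setNames(sprintf("clone%05d", cell_clone), cell_bc)
  out
}

# Random chain gene usage + CDR3, vectorized over n clonotypes. Returns one
# table per chain slot.
clone_chain_table <- function(receptor, n) {
  rand_cdr3 <- function(n) vapply(sample(30:45, n, replace = TRUE),
                                  function(len) paste(sample(c("A", "C", "G", "T"),
                                                             len, replace = TRUE),
                                                      collapse = ""), character(1))
  gpick <- function(prefix, k) sprintf("%s%d", prefix,
                                       sample.int(k, n, replace = TRUE))
  if (n == 0) return(list())
  if (receptor == "TCR") {
    list(list(chain = rep("TRA", n), v = gpick("TRAV", 40),
              d = rep(NA_character_, n), j = gpick("TRAJ", 50),
              c = rep("TRAC", n), cdr3 = rand_cdr3(n)),
         list(chain = rep("TRB", n), v = gpick("TRBV", 30),
              d = gpick("TRBD", 2), j = gpick("TRBJ", 12),
              c = gpick("TRBC", 2), cdr3 = rand_cdr3(n)))
  } else {
    light <- sample(c("IGK", "IGL"), n, replace = TRUE)
    list(list(chain = rep("IGH", n), v = gpick("IGHV", 50),
              d = gpick("IGHD", 25), j = gpick("IGHJ", 6),
              c = sample(c("IGHM", "IGHG1", "IGHA1"), n, replace = TRUE),
              cdr3 = rand_cdr3(n)),
         list(chain = light, v = sprintf("%sV%d", light,
                                         sample.int(30, n, replace = TRUE)),
              d = rep(NA_character_, n),
              j = sprintf("%sJ%d", light, sample.int(5, n, replace = TRUE)),
              c = paste0(light, "C"), cdr3 = rand_cdr3(n)))
  }
}
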