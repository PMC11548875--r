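# Shared fixtures. Simulated cohorts are memoised per test file so several
# test_that() blocks can reuse one simulation.

.fixture_env <- new.env(parent = emptyenv())

# A desk-scale cohort: 6 RECIST samples + 1 normal-tissue sample, 400-gene
# genome. Large enough for gating/CNV/clonotype recovery checks, small
# enough to simulate in a couple of seconds.
small_sim <- function(seed = 42) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(n_samples = 6,
                      samples_per_group = c(PR = 2, SD = 2, PD = 2),
                      cells_per_sample = 150, n_normal_samples = 1,
                      n_genes = 400, seed = seed)
    .fixture_env[[key]] <- simulate_cohort(cfg)
  }
  .fixture_env[[key]]
}

# Simulation plus QC and log-normalization, the entry state of most stages.
small_sim_prepped <- function(seed = 42) {
  key <- paste0("prepped_", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- small_sim(seed)
    keep <- qc_filter(sim$cohort)
    kept <- subset_cells(sim$cohort, keep)
    .fixture_env[[key]] <- list(
      sim = sim, keep = keep, kept = kept,
      truth = sim$truth$cells[keep, , drop = FALSE],
      norm = log_normalize(kept$counts))
  }
  .fixture_env[[key]]
}

# Tiny hand-built cohort for structural io/QC checks: 6 genes (2 mito),
# 4 cells across 2 samples.
tiny_cohort <- function() {
  counts <- matrix(
    c(5, 0, 1, 2,
      3, 1, 0, 4,
      0, 2, 2, 1,
      1, 0, 3, 0,
      2, 8, 1, 1,   # MT-A
      0, 7, 0, 2),  # MT-B
    nrow = 6, byrow = TRUE,
    dimnames = list(c("G1", "G2", "G3", "G4", "MT-A", "MT-B"),
                    c("c1", "c2", "c3", "c4")))
  cell_meta <- data.frame(
    barcode = colnames(counts), sample_id = c("S1", "S1", "S2", "S2"),
    patient_id = c("P1", "P1", "P2", "P2"),
    lineage = c("TNK", "Epithelial", "TNK", "B"),
    subtype = c("CD4_TN", "Malignant", "CD8_TEM", "B"),
    is_doublet = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  sample_meta <- data.frame(
    sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
    recist = c("PR", "PD"),
    response = c("responder", "non_responder"),
    tissue_origin = c("Lung", "mLN"), subtype = c("AD", "AD"),
    stage = c("IV", "IV"), smoking = c("ever", "never"),
    stringsAsFactors = FALSE)
  adt <- matrix(c(10, 2, 5, 1,
                  1, 3, 20, 2,
                  30, 2, 25, 28,
                  2, 1, 3, 2), nrow = 4, byrow = TRUE,
                dimnames = list(c("CD4", "CD8", "CD45", "CD56"),
                                colnames(counts)))
  cell_cohort(counts, cell_meta, sample_meta, adt = adt)
}

# Independent brute-force AUC over all label pairs (ties count 1/2).
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Independent exact two-sided rank-sum p by explicit enumeration.
enumerate_rank_sum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  mu <- nx * (nx + length(y) + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - mu)
  sets <- utils::combn(length(r), nx)
  devs <- abs(apply(sets, 2, function(i) sum(r[i])) - mu)
  mean(devs >= obs - 1e-9)
}

# Step-up Benjamini-Hochberg oracle.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
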