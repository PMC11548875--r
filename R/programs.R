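#' Differential-expression thresholds
#'
#' The four-way filter: |logFC| > 0.25, p < 0.01, Bonferroni-adjusted
#' p < 0.01, and detection fraction (pct) >= 0.25 in at least one group.
#'
#' @param min_abs_logfc,max_p,max_adj_p,min_pct filter values.
#' @return a `deg_thresholds` list.
#' @export
deg_thresholds <- function(min_abs_logfc = 0.25, max_p = 0.01,
                           max_adj_p = 0.01, min_pct = 0.25) {
  stopifnot(min_abs_logfc > 0, max_p > 0, max_p <= 1, max_adj_p > 0,
            max_adj_p <= 1, min_pct > 0, min_pct <= 1)
  structure(list(min_abs_logfc = min_abs_logfc, max_p = max_p,
                 max_adj_p = max_adj_p, min_pct = min_pct),
            class = "deg_thresholds")
}

#' Two-sample Wilcoxon rank-sum p-value
#'
#' Two-tailed. Normal approximation with tie-corrected variance (no
#' continuity correction); exact enumeration over all assignments when both
#' groups have at most `exact_max` observations (ties handled exactly).
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration size limit per group.
#' @return p-value.
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    idx <- utils::combn(nx + ny, nx)
    ws <- colSums(matrix(r[idx], nrow = nx))
    dev <- abs(ws - mu)
    return(mean(dev >= abs(W - mu) - 1e-9))
  }
  n <- nx + ny
  ties <- table(r)
  v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(1)
  z <- (W - mu) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Wilcoxon differential expression between two cell groups
#'
#' Genes are pre-filtered to those detected in >= `min_pct` of cells in at
#' least one group with |logFC| > `min_abs_logfc`, where logFC is the
#' difference of group means of log-normalized expression (natural log).
#' The surviving genes get a two-tailed Wilcoxon rank-sum p (exact for tiny
#' groups) and a Bonferroni adjustment over the genes actually tested. A
#' gene passes iff all four thresholds hold; `up` genes are higher in group
#' A.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param cells_a,cells_b disjoint barcode/index vectors (>= 3 cells each).
#' @param thresholds a [deg_thresholds()].
#' @return list: `table` (gene, logfc, p, adj_p, pct_a, pct_b, pass for all
#'   pre-filtered genes), `up`, `down` (gene id vectors passing all
#'   filters).
#' @export
wilcoxon_deg <- function(norm, cells_a, cells_b,
                         thresholds = deg_thresholds()) {
  if (length(intersect(cells_a, cells_b)))
    stop("cell groups overlap")
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("both groups need >= 3 cells")
  A <- norm[, cells_a, drop = FALSE]
  B <- norm[, cells_b, drop = FALSE]
  pct_a <- rowMeans(A > 0); pct_b <- rowMeans(B > 0)
  logfc <- rowMeans(A) - rowMeans(B)
  keep <- (pmax(pct_a, pct_b) >= thresholds$min_pct) &
    (abs(logfc) > thresholds$min_abs_logfc)
  genes <- rownames(norm)[keep]
  if (!length(genes)) {
    tab <- data.frame(gene = character(0), logfc = numeric(0), p = numeric(0),
                      adj_p = numeric(0), pct_a = numeric(0), pct_b = numeric(0),
                      pass = logical(0), stringsAsFactors = FALSE)
    return(list(table = tab, up = character(0), down = character(0)))
  }
  p <- vapply(genes, function(g) rank_sum_test(A[g, ], B[g, ]), numeric(1))
  adj_p <- pmin(1, p * length(genes))
  pass <- p < thresholds$max_p & adj_p < thresholds$max_adj_p
  tab <- data.frame(gene = genes, logfc = logfc[keep], p = p, adj_p = adj_p,
                    pct_a = pct_a[keep], pct_b = pct_b[keep], pass = pass,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       up = tab$gene[tab$pass & tab$logfc > 0],
       down = tab$gene[tab$pass & tab$logfc < 0])
}

#' Intersection/union DEG signatures across the three response comparisons
#'
#' Builds INT.up / INT.down (intersection) and UNION.up / UNION.down (union)
#' of the up-/down-in-responder gene sets from the three pairwise
#' comparisons (responder vs non-responder, PR vs PD, PR vs SD).
#'
#' @param deg_tables list of exactly 3 results from [wilcoxon_deg()] (group
#'   A = responder/PR side in each).
#' @return named list of four gene signatures (each a `gene_signature`).
#' @export
build_int_union <- function(deg_tables) {
  if (length(deg_tables) < 3) stop("three DEG comparisons are required")
  ups <- lapply(deg_tables, `[[`, "up")
  downs <- lapply(deg_tables, `[[`, "down")
  int_up <- Reduce(intersect, ups); int_down <- Reduce(intersect, downs)
  if (!length(int_up) && !length(int_down))
    warning("empty intersection signatures")
  list(INT.up = gene_signature("INT.up", int_up, "up"),
       INT.down = gene_signature("INT.down", int_down, "down"),
       UNION.up = gene_signature("UNION.up", Reduce(union, ups), "up"),
       UNION.down = gene_signature("UNION.down", Reduce(union, downs), "down"))
}

#' A named, directed gene set
#'
#' @param name signature name (e.g. INT.up, NMF.p1, PC2.neg).
#' @param genes unique gene ids (may be empty for a degenerate
#'   intersection).
#' @param direction "up", "down" or "neutral".
#' @param provenance free-form origin tag.
#' @return a `gene_signature` list.
#' @export
gene_signature <- function(name, genes, direction = "neutral",
                           provenance = NULL) {
  structure(list(name = name, genes = unique(genes), direction = direction,
                 provenance = provenance), class = "gene_signature")
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error ||V - WH||_F with seeded
#' random-uniform initialization and the classical multiplicative update
#' rules, which keep W and H non-negative and never increase the error.
#' Factors are ordered by total loading (descending, ties by index).
#'
#' @param v non-negative matrix (genes x cells; raw UMI counts of malignant
#'   cells in the pipeline).
#' @param rank factorization rank (default 30).
#' @param max_iter iteration cap.
#' @param tol relative-error-change stopping tolerance.
#' @param seed RNG seed of the initialization.
#' @return list of class `nmf_model`: `W` (genes x rank), `H` (rank x
#'   cells), `error` (final relative Frobenius error), `error_trace`.
#' @export
fit_nmf <- function(v, rank = 30, max_iter = 100, tol = 1e-5, seed = 1L) {
  v <- as.matrix(v)
  if (any(v < 0)) stop("NMF input must be non-negative")
  eps <- 1e-10
  nr <- nrow(v); nc <- ncol(v)
  with_seed(seed, {
    W <- matrix(stats::runif(nr * rank, 0.1, 1), nr, rank)
    H <- matrix(stats::runif(rank * nc, 0.1, 1), rank, nc)
  })
  v2 <- sum(v^2)
  err <- Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    W <- W * (v %*% t(H)) / (W %*% tcrossprod(H) + eps)
    WtV <- crossprod(W, v)
    WtWH <- crossprod(W) %*% H
    H <- H * WtV / (WtWH + eps)
    # error reusing the update cross-products (post-H-update refresh of the
    # small rank x rank pieces only)
    cross <- sum(crossprod(W, v) * H)
    wh2 <- sum((crossprod(W) %*% H) * H)
    e2 <- max(v2 - 2 * cross + wh2, 0)
    new_err <- sqrt(e2 / v2)
    trace <- c(trace, new_err)
    if (is.finite(err) && abs(err - new_err) < tol * max(err, 1e-12)) {
      err <- new_err; break
    }
    err <- new_err
  }
  total <- colSums(W) * rowSums(H)
  ord <- order(-total, seq_along(total))
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  dimnames(W) <- list(rownames(v), paste0("factor", seq_len(rank)))
  dimnames(H) <- list(colnames(W), colnames(v))
  structure(list(W = W, H = H, error = err, error_trace = trace,
                 rank = rank), class = "nmf_model")
}

#' Assign NMF factors to RECIST groups and build program signatures
#'
#' The relative loading share of factor f in group g is the mean of H[f, ]
#' over the group's cells divided by the sum of those means across groups
#' (rows sum to 1). A factor is assigned to its argmax group when that share
#' exceeds (1/G) * (1 + margin); otherwise it stays unassigned. Each group's
#' program signature is the union of its member factors' top
#' `top_genes_per_factor` genes by W loading.
#'
#' @param model an `nmf_model`.
#' @param group_labels per-cell group (RECIST) labels aligned with H
#'   columns.
#' @param top_genes_per_factor genes kept per factor (default 50).
#' @param margin assignment margin over the uniform share (default 0.25).
#' @return list: `shares` (factor x group matrix), `assignment` (named
#'   vector factor -> group or NA), `programs` (named list of
#'   `gene_signature`, one per group with >= 1 factor).
#' @export
derive_nmf_programs <- function(model, group_labels, top_genes_per_factor = 50,
                                margin = 0.25) {
  groups <- unique(as.character(group_labels))
  if (any(table(factor(group_labels, levels = groups)) == 0))
    stop("every group must have at least one cell")
  means <- sapply(groups, function(g)
    rowMeans(model$H[, group_labels == g, drop = FALSE]))
  denom <- rowSums(means)
  denom[denom == 0] <- 1
  shares <- means / denom
  G <- length(groups)
  thresh <- (1 / G) * (1 + margin)
  best <- apply(shares, 1, which.max)
  assigned <- ifelse(shares[cbind(seq_len(nrow(shares)), best)] > thresh,
                     groups[best], NA_character_)
  names(assigned) <- colnames(model$W)
  programs <- list()
  for (g in groups) {
    fs <- names(assigned)[!is.na(assigned) & assigned == g]
    if (!length(fs)) next
    genes <- unique(unlist(lapply(fs, function(f) {
      w <- model$W[, f]
      rownames(model$W)[order(-w, seq_along(w))[seq_len(min(top_genes_per_factor,
                                                            length(w)))]]
    })))
    programs[[paste0("NMF.", g)]] <-
      gene_signature(paste0("NMF.", g), genes, "up",
                     provenance = paste(fs, collapse = "+"))
  }
  list(shares = shares, assignment = assigned, programs = programs)
}

#' Top-coefficient gene modules per group
#'
#' Per module, take the `top_n` genes with the highest coefficients (ties by
#' ascending gene index); per group, the module signature is the union of
#' its modules' top-n sets.
#'
#' @param coefficient_tables named list of numeric coefficient vectors
#'   (names = gene ids), one per module.
#' @param module_groups named character vector module -> group.
#' @param top_n genes per module (default 100; shorter vectors are taken
#'   whole with a warning).
#' @return named list of `gene_signature`, one per group.
#' @export
refine_top_gene_modules <- function(coefficient_tables, module_groups,
                                    top_n = 100) {
  sets <- lapply(names(coefficient_tables), function(m) {
    co <- coefficient_tables[[m]]
    if (length(co) < top_n)
      warning("module ", m, " has fewer than ", top_n, " genes; taking all")
    k <- min(top_n, length(co))
    names(co)[order(-co, seq_along(co))[seq_len(k)]]
  })
  names(sets) <- names(coefficient_tables)
  out <- list()
  for (g in unique(module_groups)) {
    mods <- names(module_groups)[module_groups == g]
    out[[paste0("module.", g)]] <- gene_signature(
      paste0("module.", g), Reduce(union, sets[mods]), "up",
      provenance = paste(mods, collapse = "+"))
  }
  out
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# (sum of all tables, at fixed margins, no more probable than the observed).
fisher_exact_p <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(x, m, n, k) * (1 + 1e-7)])
}

#' Program-by-group enrichment odds ratios
#'
#' For each (program, group) pair, a 2x2 table of {in program vs not} x
#' {in group vs not} over cells gives an odds ratio (cross-product, with the
#' Haldane-Anscombe 0.5 correction when any cell is zero) and a two-sided
#' Fisher exact p-value. Log odds ratios are z-scored across groups within
#' each program row.
#'
#' @param cell_program per-cell program assignment (character/factor).
#' @param group_labels per-cell group labels (>= 2 groups).
#' @return data.frame (program, group, odds_ratio, p, z_log_or).
#' @export
enrichment_odds_ratio <- function(cell_program, group_labels) {
  groups <- unique(as.character(group_labels))
  if (length(groups) < 2) stop("need at least two groups")
  progs <- unique(as.character(cell_program))
  rows <- list()
  for (pr in progs) {
    for (g in groups) {
      a <- sum(cell_program == pr & group_labels == g)
      b <- sum(cell_program == pr & group_labels != g)
      c_ <- sum(cell_program != pr & group_labels == g)
      d <- sum(cell_program != pr & group_labels != g)
      tab <- matrix(c(a, c_, b, d), 2)
      or <- if (any(tab == 0)) {
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      } else (a * d) / (b * c_)
      rows[[length(rows) + 1L]] <- data.frame(
        program = pr, group = g, odds_ratio = or, p = fisher_exact_p(tab),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$z_log_or <- stats::ave(log(out$odds_ratio), out$program, FUN = function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  out
}

#' Principal-component signatures of malignant cells
#'
#' PCA (singular value decomposition of the centered, scaled matrix over the
#' highly variable genes) of malignant cells; per PC, the 30 genes with the
#' most positive loadings form the `pos` signature and the 30 most negative
#' the `neg` signature. The sign convention (largest-magnitude loading made
#' positive) makes the output deterministic across runs and cell
#' permutations.
#'
#' @param scaled genes x cells scaled matrix (HVG subset).
#' @param n_pcs components to keep (default 10).
#' @param top_genes genes per sign (default 30).
#' @return list: `signatures` (named list of `gene_signature` PC<k>.pos/.neg),
#'   `rotation` (gene loadings), `sdev`.
#' @export
pca_signatures <- function(scaled, n_pcs = 10, top_genes = 30) {
  if (nrow(scaled) < 2 * top_genes)
    stop("need at least ", 2 * top_genes, " genes")
  pc <- stats::prcomp(t(scaled), center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  rot <- pc$rotation[, seq_len(min(n_pcs, ncol(pc$rotation))), drop = FALSE]
  for (j in seq_len(ncol(rot)))
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  sigs <- list()
  for (j in seq_len(ncol(rot))) {
    w <- rot[, j]
    pos <- rownames(rot)[order(-w, seq_along(w))[seq_len(top_genes)]]
    neg <- rownames(rot)[order(w, seq_along(w))[seq_len(top_genes)]]
    sigs[[paste0("PC", j, ".pos")]] <-
      gene_signature(paste0("PC", j, ".pos"), pos, "up", provenance = "pca")
    sigs[[paste0("PC", j, ".neg")]] <-
      gene_signature(paste0("PC", j, ".neg"), neg, "down", provenance = "pca")
  }
  list(signatures = sigs, rotation = rot, sdev = pc$sdev)
}

#' Per-sample signature scores of malignant cells
#'
#' Per sample: the mean over its malignant cells of the mean log-normalized
#' expression of the signature genes, then divided by the maximum across
#' samples (max-normalized to [0, 1]). Samples without malignant cells get
#' NA.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param signature a `gene_signature` (or character gene vector).
#' @param malignant_mask logical malignant mask over cells.
#' @param sample_ids per-cell sample ids.
#' @return named numeric per-sample score.
#' @export
score_signature_per_sample <- function(norm, signature, malignant_mask,
                                       sample_ids) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  genes <- intersect(genes, rownames(norm))
  if (!length(genes)) stop("signature genes absent from the matrix")
  samples <- unique(sample_ids)
  cell_score <- colMeans(norm[genes, , drop = FALSE])
  raw <- vapply(samples, function(s) {
    sel <- malignant_mask & sample_ids == s
    if (!any(sel)) return(NA_real_)
    mean(cell_score[sel])
  }, numeric(1))
  names(raw) <- samples
  mx <- max(raw, na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) return(raw)
  raw / mx
}
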