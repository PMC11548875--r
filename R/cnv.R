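#' CNV inference parameters
#'
#' Defaults follow the conventions of expression-based CNV callers: genes
#' with mean raw count below 0.1 are dropped, the smoothing window is 101
#' genes, relative expression is clipped at +/-3, and small deviations are
#' denoised away at 1.5 x the reference signal s.d. Malignancy thresholds
#' (s.d. > 0.03 or correlation > 0.3) and the 20% epithelial reference cap
#' follow the published calling rule.
#'
#' @param expression_cutoff minimum mean raw count for a gene to enter.
#' @param window_genes moving-average window (odd, >= 3).
#' @param clip_bound symmetric clip of per-gene relative expression.
#' @param sd_threshold malignant call threshold on the per-cell signal s.d.
#' @param cor_threshold malignant call threshold on the correlation with the
#'   top-cell mean profile.
#' @param top_cell_fraction fraction of cells (ranked by s.d.) averaged into
#'   the top-cell profile.
#' @param max_reference_epithelial_fraction cap on the epithelial fraction
#'   of a sample before normal cells are spiked in.
#' @param denoise logical; zero out small deviations after centering.
#' @param noise_sd_amplifier multiple of the reference signal s.d. defining
#'   the denoising dead zone.
#' @return a `cnv_params` list.
#' @export
cnv_params <- function(expression_cutoff = 0.1, window_genes = 101,
                       clip_bound = 3.0, sd_threshold = 0.03,
                       cor_threshold = 0.3, top_cell_fraction = 0.05,
                       max_reference_epithelial_fraction = 0.20,
                       denoise = TRUE, noise_sd_amplifier = 1.5) {
  stopifnot(window_genes %% 2 == 1, window_genes >= 3,
            top_cell_fraction > 0, top_cell_fraction < 1)
  structure(list(expression_cutoff = expression_cutoff,
                 window_genes = window_genes, clip_bound = clip_bound,
                 sd_threshold = sd_threshold, cor_threshold = cor_threshold,
                 top_cell_fraction = top_cell_fraction,
                 max_reference_epithelial_fraction = max_reference_epithelial_fraction,
                 denoise = denoise, noise_sd_amplifier = noise_sd_amplifier),
            class = "cnv_params")
}

#' Order genes genomically
#'
#' Sorts genes by (chromosome order, start position); genes without a
#' position are dropped (count reported via message). The result is invariant
#' to the row order of the position table.
#'
#' @param gene_position_table data.frame (gene_id, chromosome, start, end).
#' @param gene_ids genes present in the expression matrix.
#' @param chromosomes declared ordered chromosome set (defaults to the order
#'   of first appearance after sorting chr names naturally).
#' @return data.frame (gene_id, chromosome, start) in genomic order.
#' @export
build_genomic_order <- function(gene_position_table, gene_ids,
                                chromosomes = NULL) {
  tab <- gene_position_table[gene_position_table$gene_id %in% gene_ids, ,
                             drop = FALSE]
  n_drop <- length(gene_ids) - length(unique(tab$gene_id))
  if (!nrow(tab)) stop("no overlap between gene ids and the position table")
  if (nrow(tab) < 0.5 * length(gene_ids))
    stop("positions available for fewer than 50% of genes")
  if (n_drop > 0)
    message(n_drop, " gene(s) without genomic position dropped from CNV ordering")
  if (is.null(chromosomes)) {
    chromosomes <- unique(tab$chromosome)
    num <- suppressWarnings(as.numeric(sub("^chr", "", chromosomes)))
    chromosomes <- chromosomes[order(is.na(num), num, chromosomes)]
  }
  tab$chromosome <- factor(tab$chromosome, levels = chromosomes)
  ord <- order(tab$chromosome, tab$start, tab$gene_id)
  out <- tab[ord, c("gene_id", "chromosome", "start")]
  rownames(out) <- NULL
  out
}

# Centered moving average along rows (genes) with truncated edge windows,
# computed per column via cumulative sums.
moving_average_truncated <- function(x, window) {
  n <- nrow(x)
  if (n == 1L) return(x)
  half <- (window - 1) %/% 2
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  upper <- cs[hi, , drop = FALSE]
  lower <- rbind(0, cs)[lo, , drop = FALSE]
  sweep(upper - lower, 1, hi - lo + 1, "/")
}

#' Infer a smoothed CNV expression signal
#'
#' Per gene, relative expression is the log-normalized value minus the mean
#' over reference (normal) cells, clipped; per chromosome, a centered moving
#' average over `window_genes` genes (edge windows truncated) smooths the
#' profile; each cell's profile is then median-centered and the mean
#' reference profile subtracted again (two-pass centering). When `denoise`
#' is on, deviations within `noise_sd_amplifier` x the reference signal s.d.
#' are set to zero.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param reference_cell_mask logical mask of reference (normal) cells.
#' @param gene_order output of [build_genomic_order()].
#' @param params a [cnv_params()].
#' @param counts optional raw counts aligned with `norm` for the
#'   `expression_cutoff` filter (defaults to filtering on `expm1` of norm).
#' @return list of class `cnv_profile`: `signal` (window-position x cell),
#'   `centered` (pre-denoise signal), `gene_order` (rows retained),
#'   `reference_mask`, `noise_threshold`.
#' @export
infer_cnv_signal <- function(norm, reference_cell_mask, gene_order,
                             params = cnv_params(), counts = NULL) {
  if (!any(reference_cell_mask)) stop("reference cell set is empty")
  mean_raw <- if (is.null(counts)) rowMeans(expm1(norm)) else rowMeans(as.matrix(counts))
  expressed <- rownames(norm)[mean_raw >= params$expression_cutoff]
  go <- gene_order[gene_order$gene_id %in% expressed, , drop = FALSE]
  keep_chr <- table(go$chromosome)
  small <- names(keep_chr)[keep_chr > 0 & keep_chr < 3]
  if (length(small)) {
    warning("chromosome(s) with fewer than 3 genes skipped: ",
            paste(small, collapse = ", "))
    go <- go[!(go$chromosome %in% small), , drop = FALSE]
  }
  x <- norm[go$gene_id, , drop = FALSE]
  rel <- x - rowMeans(x[, reference_cell_mask, drop = FALSE])
  rel <- clip_abs(rel, params$clip_bound)
  sig <- rel
  for (chr in unique(as.character(go$chromosome))) {
    idx <- which(go$chromosome == chr)
    sig[idx, ] <- moving_average_truncated(rel[idx, , drop = FALSE],
                                           params$window_genes)
  }
  sig <- sweep(sig, 2, apply(sig, 2, stats::median), "-")
  sig <- sig - rowMeans(sig[, reference_cell_mask, drop = FALSE])
  centered <- sig
  tau <- NA_real_
  if (isTRUE(params$denoise)) {
    tau <- params$noise_sd_amplifier *
      stats::sd(as.vector(sig[, reference_cell_mask, drop = FALSE]))
    sig[abs(sig) <= tau] <- 0
  }
  structure(list(signal = sig, centered = centered, gene_order = go,
                 reference_mask = reference_cell_mask, noise_threshold = tau),
            class = "cnv_profile")
}

#' Per-cell CNV summary: s.d. and top-cell correlation
#'
#' The s.d. is the standard deviation of a cell's signal across all window
#' positions; cells are ranked by s.d., the top `top_cell_fraction` cells'
#' profiles are averaged, and each cell's Pearson correlation with that mean
#' profile is reported. A flat-profile cell has s.d. 0 and undefined
#' correlation (returned as NA).
#'
#' @param profile a `cnv_profile` or a window x cell signal matrix.
#' @param params a [cnv_params()].
#' @return data.frame (barcode, sd, cor) with attribute `top_cells`.
#' @export
summarize_cnv_cells <- function(profile, params = cnv_params()) {
  sig <- if (inherits(profile, "cnv_profile")) profile$signal else profile
  n <- ncol(sig)
  if (n < 20) stop("fewer than 20 cells: top-fraction profile is not meaningful")
  sds <- sqrt(colSums(sweep(sig, 2, colMeans(sig), "-")^2) / (nrow(sig) - 1))
  n_top <- max(1L, ceiling(params$top_cell_fraction * n))
  top <- order(-sds, seq_len(n))[seq_len(n_top)]
  top_mean <- rowMeans(sig[, top, drop = FALSE])
  cors <- suppressWarnings(as.vector(stats::cor(sig, top_mean)))
  out <- data.frame(barcode = colnames(sig) %||% as.character(seq_len(n)),
                    sd = sds, cor = cors, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "top_cells") <- top
  out
}

#' Threshold malignant call
#'
#' A cancer-candidate cell is malignant iff its signal s.d. exceeds 0.03 or
#' its correlation with the top-cell profile exceeds 0.3 (NA correlation
#' counts as below threshold). Only candidate (epithelial) cells are called;
#' immune/stromal cells are never called.
#'
#' @param summary output of [summarize_cnv_cells()].
#' @param params a [cnv_params()].
#' @param candidate_mask logical mask of cancer-candidate cells (default:
#'   all).
#' @return logical vector over the summary's cells; FALSE outside the
#'   candidate mask.
#' @export
call_malignant_threshold <- function(summary, params = cnv_params(),
                                     candidate_mask = NULL) {
  call <- (summary$sd > params$sd_threshold) |
    (!is.na(summary$cor) & summary$cor > params$cor_threshold)
  if (!is.null(candidate_mask)) call <- call & candidate_mask
  stats::setNames(call, summary$barcode)
}

# Deterministic two-component 1-D Gaussian EM with a variance floor;
# initialized at the 25th/75th percentiles so repeated runs agree exactly.
em_gmm2 <- function(x, max_iter = 200, tol = 1e-8, var_floor = 1e-12) {
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (diff(mu) == 0) mu <- mu + c(-1e-6, 1e-6)
  s2 <- rep(max(stats::var(x), var_floor), 2)
  pi_k <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi_k[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- pi_k[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d2 / tot
    pi_k <- c(1 - mean(g), mean(g))
    if (any(pi_k < 1e-9)) break
    mu <- c(sum((1 - g) * x) / sum(1 - g), sum(g * x) / sum(g))
    s2 <- c(max(sum((1 - g) * (x - mu[1])^2) / sum(1 - g), var_floor),
            max(sum(g * (x - mu[2])^2) / sum(g), var_floor))
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, s2 = s2, pi = pi_k, posterior2 = g)
}

#' Mixture-model aneuploid call
#'
#' Fits a two-component Gaussian mixture to the per-cell signal variance;
#' cells assigned to the higher-mean component are called aneuploid. If the
#' two component means are within 1e-3 the fit is degenerate and all cells
#' are called diploid (with a warning). The EM is deterministically
#' initialized, so repeated runs give identical calls.
#'
#' @param profile a `cnv_profile` or signal matrix.
#' @return logical per-cell vector (TRUE = aneuploid).
#' @export
aneuploid_cluster_call <- function(profile) {
  sig <- if (inherits(profile, "cnv_profile")) profile$signal else profile
  v <- apply(sig, 2, stats::var)
  nm <- colnames(sig) %||% as.character(seq_along(v))
  if (stats::sd(v) == 0) {
    warning("degenerate variance distribution; all cells called diploid")
    return(stats::setNames(rep(FALSE, length(v)), nm))
  }
  fit <- em_gmm2(v)
  if (abs(diff(fit$mu)) < 1e-3) {
    warning("mixture components indistinguishable; all cells called diploid")
    return(stats::setNames(rep(FALSE, length(v)), nm))
  }
  hi <- which.max(fit$mu)
  post_hi <- if (hi == 2) fit$posterior2 else 1 - fit$posterior2
  stats::setNames(post_hi > 0.5, nm)
}

#' Union consensus of two malignant callers
#'
#' @param call_a,call_b logical vectors over the same cell universe (named
#'   vectors are checked for matching names).
#' @return logical OR of the two calls.
#' @export
consensus_union <- function(call_a, call_b) {
  if (length(call_a) != length(call_b))
    stop("call universes differ in size")
  if (!is.null(names(call_a)) && !is.null(names(call_b)) &&
      !identical(names(call_a), names(call_b)))
    stop("call universes differ (cell names do not match)")
  call_a | call_b
}

#' Per-sample malignant-cell identification
#'
#' For each sample: reference cells are the immune cells (T/NK, B/plasma,
#' myeloid, mast); candidates are the epithelial cells. If the epithelial
#' fraction of the sample exceeds the configured cap, normal cells from
#' `normal_pool` (barcodes of cells outside the sample, e.g. normal-tissue
#' profiles) are spiked into the run as extra reference cells. The CNV
#' signal, the s.d./correlation summary, the threshold call, the mixture
#' aneuploid call and their union consensus are computed per sample.
#'
#' @param norm genes x cells log-normalized matrix (all samples).
#' @param counts aligned raw counts (for the expression filter).
#' @param cell_meta per-cell metadata with `barcode`, `sample_id`, `lineage`.
#' @param gene_order output of [build_genomic_order()].
#' @param params a [cnv_params()].
#' @param normal_pool optional barcodes usable as spike-in reference (e.g.
#'   epithelial cells from normal-tissue samples).
#' @param tumor_samples samples to call (default: all in `cell_meta`).
#' @return data.frame (barcode, sample_id, sd, cor, threshold_call,
#'   aneuploid_call, consensus_call) for all epithelial candidate cells.
#' @export
call_malignant_cells <- function(norm, counts, cell_meta, gene_order,
                                 params = cnv_params(), normal_pool = NULL,
                                 tumor_samples = unique(cell_meta$sample_id)) {
  immune <- c("TNK", "B", "Myeloid", "Mast")
  out <- list()
  for (s in tumor_samples) {
    cm <- cell_meta[cell_meta$sample_id == s, , drop = FALSE]
    cand <- cm$barcode[cm$lineage == "Epithelial"]
    if (!length(cand)) next
    ref <- cm$barcode[cm$lineage %in% immune]
    cells <- c(ref, cand)
    epi_frac <- length(cand) / length(cells)
    if (epi_frac > params$max_reference_epithelial_fraction &&
        length(normal_pool)) {
      # dilute until the sample's epithelial fraction is strictly below cap
      need <- ceiling(length(cand) / params$max_reference_epithelial_fraction) -
        length(cells) + 1L
      spike <- utils::head(setdiff(normal_pool, cells), max(need, 0))
      ref <- c(ref, spike)
      cells <- c(ref, cand)
    }
    ref_mask <- cells %in% ref
    prof <- infer_cnv_signal(norm[, cells, drop = FALSE], ref_mask, gene_order,
                             params, counts = counts[, cells, drop = FALSE])
    smry <- summarize_cnv_cells(prof, params)
    cand_mask <- smry$barcode %in% cand
    thr <- call_malignant_threshold(smry, params, cand_mask)
    ane <- aneuploid_cluster_call(prof) & cand_mask
    cons <- consensus_union(thr, unname(ane))
    keep <- cand_mask
    out[[s]] <- data.frame(barcode = smry$barcode[keep], sample_id = s,
                           sd = smry$sd[keep], cor = smry$cor[keep],
                           threshold_call = thr[keep], aneuploid_call = ane[keep],
                           consensus_call = cons[keep], row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
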