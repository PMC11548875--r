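#' Quality-control thresholds
#'
#' Cells are kept when the mitochondrial fraction is below 20%, more than 200
#' genes are detected, and the cell is not a flagged multiplet. Both
#' inequalities are strict, so boundary cells (exactly 20% mitochondrial
#' counts or exactly 200 detected genes) are removed.
#'
#' @param mito_fraction_max maximum mitochondrial count fraction (exclusive).
#' @param min_genes_detected detected-gene threshold (exclusive: keep > n).
#' @param mito_gene_prefix prefix identifying mitochondrial genes.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(mito_fraction_max = 0.20, min_genes_detected = 200,
                          mito_gene_prefix = "MT-") {
  stopifnot(mito_fraction_max > 0, mito_fraction_max <= 1,
            min_genes_detected >= 0)
  structure(list(mito_fraction_max = mito_fraction_max,
                 min_genes_detected = min_genes_detected,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_thresholds")
}

#' Cell quality filter
#'
#' @param cohort a `cell_cohort` (the doublet flag in `cell_meta$is_doublet`
#'   is consumed as given; multiplet prediction itself is upstream input,
#'   not computed here).
#' @param thresholds a [qc_thresholds()].
#' @return logical keep-mask over cells, with a `metrics` attribute
#'   (data.frame: barcode, n_genes_detected, mito_fraction, is_doublet,
#'   keep).
#' @export
qc_filter <- function(cohort, thresholds = qc_thresholds()) {
  counts <- as.matrix(cohort$counts)
  mito <- startsWith(rownames(counts), thresholds$mito_gene_prefix)
  tot <- colSums(counts)
  if (!any(mito)) {
    warning("no mitochondrial genes found with prefix '",
            thresholds$mito_gene_prefix, "'; mito criterion passes vacuously")
    mito_frac <- rep(0, ncol(counts))
  } else {
    mito_frac <- colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1)
  }
  n_det <- colSums(counts > 0)
  doublet <- cohort$cell_meta$is_doublet %||% rep(FALSE, ncol(counts))
  keep <- (mito_frac < thresholds$mito_fraction_max) &
    (n_det > thresholds$min_genes_detected) & !doublet
  attr(keep, "metrics") <- data.frame(
    barcode = colnames(counts), n_genes_detected = n_det,
    mito_fraction = mito_frac, is_doublet = doublet, keep = keep,
    row.names = NULL, stringsAsFactors = FALSE)
  keep
}

#' Log-normalize UMI counts
#'
#' `value = ln(1 + count / cell_total * scale_factor)`, the standard
#' library-size normalization with natural-log transform and a 10,000-count
#' scale factor.
#'
#' @param counts genes x cells count matrix (dense or sparse).
#' @param scale_factor library-size scale factor.
#' @return dense genes x cells matrix of log-normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[tot <= 0], 3), collapse = ", "),
         " (should have been removed by QC)")
  log1p(sweep(counts, 2, scale_factor / tot, "*"))
}

#' Select highly variable genes (vst-style standardized variance)
#'
#' Fits a local polynomial regression (loess, span 0.3) of log10(variance)
#' on log10(mean) over raw counts, standardizes each gene by its predicted
#' standard deviation with values clipped at sqrt(n_cells), and ranks genes
#' by the variance of the standardized values. Ties are broken by ascending
#' gene index, so the output is deterministic.
#'
#' @param counts genes x cells raw count matrix.
#' @param n number of genes to return.
#' @param loess_span span of the mean-variance trend fit.
#' @return character vector of the top `n` gene ids, ranked; the full ranking
#'   statistic is attached as attribute `std_variance`.
#' @export
select_hvg <- function(counts, n = 2000, loess_span = 0.3) {
  counts <- as.matrix(counts)
  if (n > nrow(counts)) stop("n exceeds the number of genes")
  mu <- rowMeans(counts)
  v <- row_vars(counts)
  nz <- v > 0 & mu > 0
  if (sum(nz) < n) stop("fewer than n genes with nonzero variance")
  fit <- stats::loess(log10(v[nz]) ~ log10(mu[nz]), span = loess_span,
                      degree = 2)
  sd_exp <- rep(NA_real_, nrow(counts))
  sd_exp[nz] <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(ncol(counts))
  stdvar <- rep(0, nrow(counts))
  z <- (counts[nz, , drop = FALSE] - mu[nz]) / sd_exp[nz]
  z <- pmin(z, clip)
  stdvar[nz] <- row_vars(z)
  ord <- order(-stdvar, seq_along(stdvar))
  out <- rownames(counts)[ord[seq_len(n)]]
  attr(out, "std_variance") <- stats::setNames(stdvar, rownames(counts))
  out
}

#' Scale expression with covariate regression
#'
#' Per gene: ordinary least squares of expression on the covariates (e.g.,
#' cell-cycle S and G2M scores), residuals z-scored across cells and clipped.
#' With no covariates this reduces to a per-gene z-score.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param covariates optional data.frame / matrix of per-cell numeric
#'   covariates; collinear columns are dropped with a warning.
#' @param clip_bound symmetric clipping bound of the scaled values.
#' @return genes x cells scaled matrix.
#' @export
scale_and_regress <- function(norm, covariates = NULL, clip_bound = 10) {
  norm <- as.matrix(norm)
  n <- ncol(norm)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(covariates)
    X2 <- cbind(X, cv)
    qrx <- qr(X2)
    if (qrx$rank < ncol(X2)) {
      drop_idx <- qrx$pivot[seq(qrx$rank + 1, ncol(X2))]
      warning("dropping collinear covariate(s): ",
              paste(colnames(X2)[drop_idx], collapse = ", "))
      X2 <- X2[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    }
    X <- X2
  }
  # residuals for all genes at once: R = Y - Y X (X'X)^-1 X'
  XtXi <- solve(crossprod(X))
  B <- (norm %*% X) %*% XtXi
  R <- norm - B %*% t(X)
  s <- sqrt(row_vars(R))
  # a gene fully explained by the covariates has only float-noise residuals;
  # rescaling those to unit variance would amplify numerical noise
  degenerate <- s <= 1e-8 * (sqrt(row_vars(norm)) + 1e-300)
  R[degenerate, ] <- 0
  s[degenerate | s == 0] <- 1
  clip_abs(R / s, clip_bound)
}

#' Score cells by mean expression of a gene set
#'
#' The score is the mean log-normalized expression over the set's genes that
#' are present in the matrix; absent genes are dropped with a warning.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param gene_set character vector of gene ids.
#' @return numeric per-cell score (named by barcode).
#' @export
score_gene_set <- function(norm, gene_set) {
  present <- intersect(gene_set, rownames(norm))
  if (!length(present))
    stop("none of the gene-set genes are present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present), " gene(s) of the set absent; dropped")
  colMeans(norm[present, , drop = FALSE])
}

#' Built-in cell-cycle gene sets
#'
#' S-phase and G2/M gene lists shipped as a plain-text fixture
#' (`extdata/cell_cycle_genes.tsv`); both are configurable inputs to
#' [scale_and_regress()] via [score_gene_set()].
#'
#' @return list with character vectors `S` and `G2M`.
#' @export
cell_cycle_genes <- function() {
  path <- system.file("extdata", "cell_cycle_genes.tsv", package = "sciri")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  split(tab$gene, tab$phase)
}
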