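#' ADT gating parameters
#'
#' @param adt_percentile percentile (0-100) of the transformed ADT level used
#'   as the positivity cutoff; computed over CD3+ cells with linear
#'   interpolation and a strict ">" boundary.
#' @param cd3_genes RNA genes defining CD3 positivity (any raw count > 0).
#' @param nk_marker_genes NK marker genes scored in CD3- cells.
#' @param unassigned_prob_threshold minimum class probability for the
#'   supervised classifier to assign a label.
#' @param adt_transform "clr" (centered log-ratio of log1p ADT per cell,
#'   robust to per-cell ADT depth) or "raw".
#' @param n_pcs principal components used by the supervised classifier.
#' @return an `adt_gate_params` list.
#' @export
adt_gate_params <- function(adt_percentile = 55,
                            cd3_genes = c("CD3D", "CD3E", "CD3G"),
                            nk_marker_genes = c("XCL1", "NCAM1", "KLRD1", "KLRF1"),
                            unassigned_prob_threshold = 0.55,
                            adt_transform = c("clr", "raw"),
                            n_pcs = 30) {
  stopifnot(adt_percentile > 0, adt_percentile < 100)
  structure(list(adt_percentile = adt_percentile, cd3_genes = cd3_genes,
                 nk_marker_genes = nk_marker_genes,
                 unassigned_prob_threshold = unassigned_prob_threshold,
                 adt_transform = match.arg(adt_transform), n_pcs = n_pcs),
            class = "adt_gate_params")
}

#' CD3 positivity gate
#'
#' A cell is CD3+ iff any of CD3D, CD3E, CD3G has a raw count (equivalently,
#' a positive log-normalized value) above zero.
#'
#' @param expr genes x cells matrix (raw counts or log-normalized values;
#'   zeros coincide).
#' @param cd3_genes the CD3 gene set.
#' @return logical per-cell vector.
#' @export
gate_cd3 <- function(expr, cd3_genes = c("CD3D", "CD3E", "CD3G")) {
  present <- intersect(cd3_genes, rownames(expr))
  if (!length(present)) stop("none of the CD3 genes are present")
  sub <- as.matrix(expr[present, , drop = FALSE]) # sparse inputs welcome
  colSums(sub > 0) > 0
}

# Centered log-ratio of log1p ADT counts, per cell.
adt_clr <- function(adt) {
  lx <- log1p(as.matrix(adt))
  sweep(lx, 2, colMeans(lx), "-")
}

#' ADT CD4/CD8 lineage gate over CD3+ cells
#'
#' Per marker, the cutoff is the 55th percentile (linear interpolation) of
#' the transformed ADT level over CD3+ cells; a cell is marker-positive iff
#' strictly above the cutoff. CD4+ only -> CD4T; CD8+ only -> CD8T; both ->
#' ambiguous; neither -> unassigned. Because the gate is percentile-based it
#' is invariant to any strictly monotone per-marker transform of the ADT
#' values.
#'
#' @param adt markers x cells ADT count matrix (rows must include "CD4" and
#'   "CD8").
#' @param cd3_mask logical CD3+ mask over the same cells.
#' @param params an [adt_gate_params()].
#' @return factor over CD3+ cells with levels CD4T/CD8T/ambiguous/unassigned,
#'   named by barcode.
#' @export
gate_adt_lineage <- function(adt, cd3_mask, params = adt_gate_params()) {
  need <- c("CD4", "CD8")
  if (!all(need %in% rownames(adt)))
    stop("ADT matrix must contain CD4 and CD8 rows")
  x <- if (params$adt_transform == "clr") adt_clr(adt) else as.matrix(adt)
  x <- x[, cd3_mask, drop = FALSE]
  pos <- sapply(need, function(m) {
    cutoff <- stats::quantile(x[m, ], params$adt_percentile / 100,
                              names = FALSE, type = 7)
    x[m, ] > cutoff
  })
  lab <- ifelse(pos[, "CD4"] & !pos[, "CD8"], "CD4T",
         ifelse(pos[, "CD8"] & !pos[, "CD4"], "CD8T",
         ifelse(pos[, "CD4"] & pos[, "CD8"], "ambiguous", "unassigned")))
  factor(stats::setNames(lab, colnames(x)),
         levels = c("CD4T", "CD8T", "ambiguous", "unassigned"))
}

#' NK gate over CD3- cells
#'
#' The NK score of a cell is the mean log-normalized expression of the NK
#' marker genes present. Mirroring the ADT convention, the cutoff is the
#' 55th percentile of the score among the CD3- cells supplied, with a strict
#' ">" boundary; a CD3- cell is NK iff its score exceeds the cutoff.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param cd3_mask logical CD3+ mask; only CD3- cells are evaluated.
#' @param params an [adt_gate_params()].
#' @return logical vector over CD3- cells, named by barcode.
#' @export
gate_nk <- function(norm, cd3_mask, params = adt_gate_params()) {
  present <- intersect(params$nk_marker_genes, rownames(norm))
  if (!length(present)) stop("no NK marker genes present")
  score <- colMeans(norm[present, !cd3_mask, drop = FALSE])
  cutoff <- stats::quantile(score, params$adt_percentile / 100,
                            names = FALSE, type = 7)
  score > cutoff
}

#' Supervised propagation of gate labels
#'
#' Projects reference and query cells into the reference's top principal
#' components (default 30) of the scaled expression matrix and fits a
#' multinomial logistic classifier on the reference; a query cell is labeled
#' when the maximum class probability reaches the reject threshold, else it
#' stays ambiguous. A probabilistic classifier with a reject option is the
#' contract; gate-sourced labels are never overwritten.
#'
#' @param reference_labels factor/character labels of the reference cells
#'   (levels among CD4T/CD8T/NK), named by barcode.
#' @param scaled genes x cells scaled matrix containing reference and query
#'   cells.
#' @param query_cells barcodes (or indices) of the cells to classify.
#' @param params an [adt_gate_params()].
#' @return data.frame (barcode, label, probability) for the query cells.
#' @export
train_and_classify <- function(reference_labels, scaled, query_cells,
                               params = adt_gate_params()) {
  ref_bc <- names(reference_labels)
  if (is.null(ref_bc)) stop("reference_labels must be named by barcode")
  tab <- table(reference_labels)
  if (length(tab) < 2 || any(tab < 20))
    stop("each reference class needs >= 20 cells (got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "),
         "); review the gate thresholds")
  Xr <- t(scaled[, ref_bc, drop = FALSE])
  k <- min(params$n_pcs, ncol(Xr) - 1, nrow(Xr) - 1)
  pc <- stats::prcomp(Xr, center = TRUE, scale. = FALSE, rank. = k)
  Zr <- pc$x[, seq_len(k), drop = FALSE]
  if (is.character(query_cells) || is.factor(query_cells))
    query_cells <- as.character(query_cells)
  Xq <- t(scaled[, query_cells, drop = FALSE])
  Zq <- sweep(Xq, 2, pc$center, "-") %*% pc$rotation[, seq_len(k), drop = FALSE]
  df_r <- data.frame(label = factor(as.character(reference_labels)), Zr)
  fit <- nnet::multinom(label ~ ., data = df_r, trace = FALSE,
                        maxit = 200, MaxNWts = 5000)
  pr <- stats::predict(fit, newdata = data.frame(Zq), type = "probs")
  if (is.null(dim(pr))) {
    # two-class fits return P(second level) as a bare vector
    pr <- cbind(1 - pr, pr)
    colnames(pr) <- fit$lev
  } else if (is.null(colnames(pr))) colnames(pr) <- fit$lev
  best <- max.col(pr, ties.method = "first")
  prob <- pr[cbind(seq_len(nrow(pr)), best)]
  label <- colnames(pr)[best]
  label[prob < params$unassigned_prob_threshold] <- "ambiguous"
  data.frame(barcode = rownames(Xq), label = label, probability = prob,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition T/NK cells into CD4+ T, CD8+ T and NK
#'
#' Runs the CD3 gate, the ADT CD4/CD8 gate (cutoffs over CD3+ cells) and the
#' NK gate (cutoff over all CD3- cells supplied), then propagates the
#' gate-confident labels to the remaining T/NK cells with the supervised
#' classifier. Every T/NK cell ends with exactly one label among
#' CD4T/CD8T/NK/ambiguous; gate labels are never overwritten.
#'
#' @param counts genes x cells raw counts (all cells; used for the CD3 gate).
#' @param norm matching log-normalized matrix.
#' @param scaled matching scaled matrix (classifier feature space).
#' @param adt ADT matrix over the same cells.
#' @param tnk_cells barcodes of the cells in the T/NK compartment.
#' @param params an [adt_gate_params()].
#' @return data.frame (barcode, label, source = gate/classifier,
#'   probability) over `tnk_cells`.
#' @export
classify_tnk <- function(counts, norm, scaled, adt, tnk_cells,
                         params = adt_gate_params()) {
  cd3 <- gate_cd3(counts, params$cd3_genes)
  adt_lab <- gate_adt_lineage(adt, cd3, params)
  nk <- gate_nk(norm, cd3, params)
  lab <- stats::setNames(rep(NA_character_, length(tnk_cells)), tnk_cells)
  al <- as.character(adt_lab[intersect(names(adt_lab), tnk_cells)])
  names(al) <- intersect(names(adt_lab), tnk_cells)
  lab[names(al)[al == "CD4T"]] <- "CD4T"
  lab[names(al)[al == "CD8T"]] <- "CD8T"
  lab[names(al)[al == "ambiguous"]] <- "ambiguous"
  nk_bc <- intersect(names(nk)[nk], tnk_cells)
  lab[nk_bc] <- "NK"
  source <- ifelse(is.na(lab), "classifier", "gate")
  prob <- stats::setNames(rep(NA_real_, length(lab)), names(lab))
  query <- names(lab)[is.na(lab)]
  if (length(query)) {
    ref <- lab[!is.na(lab) & lab %in% c("CD4T", "CD8T", "NK")]
    cls <- train_and_classify(factor(ref), scaled, query, params)
    lab[cls$barcode] <- cls$label
    prob[cls$barcode] <- cls$probability
  }
  data.frame(barcode = names(lab), label = unname(lab), source = unname(source),
             probability = unname(prob), row.names = NULL,
             stringsAsFactors = FALSE)
}
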