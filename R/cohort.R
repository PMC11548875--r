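#' Assemble a single-cell cohort object
#'
#' A `cell_cohort` bundles everything the pipeline consumes: a gene-by-cell UMI
#' count matrix, an optional ADT (antibody-derived tag) marker-by-cell count
#' matrix, per-cell metadata (sample, patient, lineage, doublet flag and, for
#' synthetic cohorts, ground-truth labels), per-sample clinical metadata
#' (RECIST category, responder status, tissue origin, subtype, stage, smoking)
#' and a gene genomic-position table used for CNV inference.
#'
#' @param counts non-negative integer matrix, genes x cells, with dimnames.
#' @param cell_meta data.frame with one row per cell; must contain `barcode`
#'   and `sample_id`.
#' @param sample_meta data.frame with one row per sample; must contain
#'   `sample_id`, `recist` (one of PR/SD/PD) and `response`
#'   ("responder"/"non_responder"). Responders are PR patients; SD and PD
#'   patients are non-responders.
#' @param adt optional non-negative matrix, ADT markers x cells.
#' @param gene_positions optional data.frame (`gene_id`, `chromosome`,
#'   `start`, `end`), 1-based base-pair coordinates.
#' @return an object of class `cell_cohort`.
#' @export
cell_cohort <- function(counts, cell_meta, sample_meta, adt = NULL,
                        gene_positions = NULL) {
  obj <- structure(
    list(counts = counts, adt = adt, cell_meta = cell_meta,
         sample_meta = sample_meta, gene_positions = gene_positions),
    class = "cell_cohort")
  validate_cohort(obj)
  obj
}

#' Validate cell_cohort invariants
#'
#' Checks the structural contract: column count of `counts` equals the number
#' of barcodes and `cell_meta` rows, every `cell_meta$sample_id` appears in
#' `sample_meta`, barcodes are unique, and RECIST/response labels are mutually
#' consistent (PR = responder; SD, PD = non-responder).
#'
#' @param x a `cell_cohort`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cell_cohort"))
  counts <- x$counts
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and cell dimnames")
  bc <- colnames(counts)
  if (anyDuplicated(bc))
    stop("duplicate cell barcodes: ", paste(unique(bc[duplicated(bc)])[1], collapse = ", "))
  if (nrow(x$cell_meta) != ncol(counts))
    stop("cell_meta rows (", nrow(x$cell_meta), ") != number of cells (", ncol(counts), ")")
  if (!identical(as.character(x$cell_meta$barcode), bc))
    stop("cell_meta$barcode must match counts column names in order")
  miss <- setdiff(unique(x$cell_meta$sample_id), x$sample_meta$sample_id)
  if (length(miss))
    stop("cell_meta sample_id absent from sample_meta: ", paste(miss, collapse = ", "))
  sm <- x$sample_meta
  if (!is.null(sm$recist)) {
    # NA = normal-tissue / non-evaluable sample
    if (!all(is.na(sm$recist) | sm$recist %in% c("PR", "SD", "PD")))
      stop("recist must be one of PR, SD, PD (or NA for normal tissue)")
    expect <- ifelse(sm$recist == "PR", "responder", "non_responder")
    ok <- is.na(sm$recist) | (!is.na(sm$response) & sm$response == expect)
    if (!is.null(sm$response) && !all(ok))
      stop("response inconsistent with RECIST (PR = responder; SD/PD = non-responder)")
  }
  if (!is.null(x$adt)) {
    if (ncol(x$adt) != ncol(counts)) stop("adt must have one column per cell")
    if (any(x$adt < 0)) stop("adt counts must be non-negative")
  }
  if (!is.null(x$gene_positions)) validate_gene_positions(x$gene_positions)
  invisible(x)
}

#' Validate a gene genomic-position table
#'
#' @param tab data.frame with `gene_id`, `chromosome`, `start`, `end`.
#' @param chromosomes optional declared ordered chromosome set.
#' @return `tab`, invisibly.
#' @export
validate_gene_positions <- function(tab, chromosomes = NULL) {
  need <- c("gene_id", "chromosome", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene position table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$start > tab$end)) stop("gene position start > end")
  if (!is.null(chromosomes) && !all(tab$chromosome %in% chromosomes))
    stop("chromosome outside declared set")
  invisible(tab)
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat("cell_cohort: ", nrow(x$counts), " genes x ", ncol(x$counts), " cells, ",
      nrow(x$sample_meta), " samples", sep = "")
  if (!is.null(x$adt)) cat(", ", nrow(x$adt), " ADT markers", sep = "")
  cat("\n")
  invisible(x)
}

#' Subset a cohort to a set of cells
#'
#' @param cohort a `cell_cohort`.
#' @param cells logical mask or index vector over cells.
#' @return a `cell_cohort` restricted to `cells`; sample metadata is kept for
#'   samples that still have cells.
#' @export
subset_cells <- function(cohort, cells) {
  counts <- cohort$counts[, cells, drop = FALSE]
  cm <- cohort$cell_meta[cells, , drop = FALSE]
  rownames(cm) <- NULL
  sm <- cohort$sample_meta[cohort$sample_meta$sample_id %in% unique(cm$sample_id), ,
                           drop = FALSE]
  rownames(sm) <- NULL
  cell_cohort(counts, cm, sm,
              adt = if (!is.null(cohort$adt)) cohort$adt[, cells, drop = FALSE],
              gene_positions = cohort$gene_positions)
}
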