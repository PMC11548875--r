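#' Clone-size class bins
#'
#' Half-open upper bounds on clone frequency n: Single (n = 1), Small
#' (1 < n <= 5), Medium (5 < n <= 10), Large (10 < n <= 20), Hyperexpanded
#' (n > 20).
#'
#' @param bounds named, strictly increasing upper bounds; the last must be
#'   `Inf`.
#' @return a `clone_size_bins` object.
#' @export
clone_size_bins <- function(bounds = c(Single = 1, Small = 5, Medium = 10,
                                       Large = 20, Hyperexpanded = Inf)) {
  if (any(diff(bounds) <= 0)) stop("bounds must be strictly increasing")
  structure(bounds, class = "clone_size_bins")
}

#' Call clonotypes from paired-chain contigs
#'
#' Keeps only cells with a complete receptor pair (TRA+TRB for TCR; IGH plus
#' IGK or IGL for BCR); when a cell has several contigs for one chain slot,
#' the highest-UMI contig is used (ties broken by lexicographic CDR3
#' nucleotide sequence). The clonotype key concatenates both chains' V(D)JC
#' genes and CDR3 nucleotide sequences (the "gene+nt" rule). Unpaired cells
#' are excluded silently (count reported via message).
#'
#' @param contigs contig table from [read_vdj_contigs()] /
#'   [simulate_repertoire()].
#' @param receptor "TCR" or "BCR".
#' @return data.frame (barcode, clonotype_id) with one row per paired cell.
#' @export
call_clonotypes <- function(contigs, receptor = c("TCR", "BCR")) {
  receptor <- match.arg(receptor)
  slots <- if (receptor == "TCR") {
    list(first = "TRA", second = "TRB")
  } else list(first = "IGH", second = c("IGK", "IGL"))
  if (is.null(contigs$umis)) contigs$umis <- rep(1L, nrow(contigs))
  # per (cell, chain slot): keep the highest-UMI contig, ties broken by
  # lexicographically smallest CDR3 nucleotide sequence
  best_of <- function(slot_chains) {
    sub <- contigs[contigs$chain %in% slot_chains, , drop = FALSE]
    if (!nrow(sub)) return(sub)
    sub <- sub[order(sub$barcode, -sub$umis, sub$cdr3_nt), , drop = FALSE]
    sub[!duplicated(sub$barcode), , drop = FALSE]
  }
  key_of <- function(tab) paste(tab$v_gene,
                                ifelse(is.na(tab$d_gene), "None", tab$d_gene),
                                tab$j_gene, tab$c_gene, tab$cdr3_nt, sep = ".")
  c1 <- best_of(slots$first)   # note: "second" may span two chains (IGK/IGL)
  c2 <- best_of(slots$second)
  paired <- intersect(c1$barcode, c2$barcode)
  dropped <- length(unique(contigs$barcode)) - length(paired)
  if (dropped) message(dropped, " cell(s) without a complete chain pair excluded")
  k <- paste(key_of(c1[match(paired, c1$barcode), , drop = FALSE]),
             key_of(c2[match(paired, c2$barcode), , drop = FALSE]), sep = "_")
  data.frame(barcode = paired,
             clonotype_id = sprintf("ct%04d", as.integer(factor(k))),
             stringsAsFactors = FALSE)
}

#' Clone-size classes and relative clone size
#'
#' Clone size is the number of paired cells sharing a clonotype id within a
#' (sample, compartment) pool; the size class applies the configured bins
#' (n = 1 Single, <= 5 Small, <= 10 Medium, <= 20 Large, else
#' Hyperexpanded); the relative clone size divides by the total number of
#' paired cells in the cell's compartment pool.
#'
#' @param table output of [call_clonotypes()].
#' @param bins a [clone_size_bins()].
#' @param compartment per-cell compartment (e.g. CD4T/CD8T/B) aligned with
#'   `table` rows; optional (single pool when absent).
#' @param sample_ids per-cell sample ids aligned with `table` rows; optional.
#' @return `table` with `clone_size`, `size_class`, `relative_clone_size`
#'   (and `compartment`/`sample_id` when supplied).
#' @export
classify_clone_sizes <- function(table, bins = clone_size_bins(),
                                 compartment = NULL, sample_ids = NULL) {
  pool <- rep("all", nrow(table))
  if (!is.null(compartment)) {
    table$compartment <- compartment
    pool <- paste(pool, compartment)
  }
  if (!is.null(sample_ids)) {
    table$sample_id <- sample_ids
    pool <- paste(pool, sample_ids)
  }
  key <- paste(pool, table$clonotype_id)
  table$clone_size <- stats::ave(seq_len(nrow(table)), key, FUN = length)
  pool_total <- stats::ave(seq_len(nrow(table)), pool, FUN = length)
  table$relative_clone_size <- table$clone_size / pool_total
  bounds <- unclass(bins)
  table$size_class <- names(bounds)[
    vapply(table$clone_size, function(n) which(n <= bounds)[1], integer(1))]
  table
}

#' T cell functional gene sets
#'
#' The regulatory and cytotoxic programs used to score T cell functional
#' features.
#'
#' @return list with `regulatory` and `cytotoxic` gene vectors.
#' @export
functional_gene_sets <- function() {
  list(regulatory = c("ICOS", "FOXP3", "IKZF2", "LAYN", "TNFRSF18", "CTLA4",
                      "IL21R", "BATF", "CCR8", "IL2RA", "TNFRSF4"),
       cytotoxic = c("CX3CR1", "PRF1", "GZMA", "GZMB", "GZMH", "GNLY",
                     "KLRG1", "NKG7"))
}

#' Per-cell regulatory and cytotoxic scores
#'
#' Mean log-normalized expression of each functional gene set (via
#' [score_gene_set()]).
#'
#' @param norm genes x cells log-normalized matrix.
#' @param sets list of gene sets (default [functional_gene_sets()]).
#' @return data.frame (barcode, one column per set).
#' @export
functional_scores <- function(norm, sets = functional_gene_sets()) {
  out <- data.frame(barcode = colnames(norm), stringsAsFactors = FALSE)
  for (nm in names(sets)) out[[nm]] <- score_gene_set(norm, sets[[nm]])
  out
}
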