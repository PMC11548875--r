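#' Read a 10x-style Matrix Market count directory
#'
#' Reads the Cell Ranger triplet dialect: `matrix.mtx` (1-based sparse
#' triplets, genes as rows), `barcodes.tsv` (one barcode per line) and
#' `features.tsv` (gene id, gene name, feature type). Gzipped variants are
#' accepted.
#'
#' @param dir_path directory containing the triplet files.
#' @return list with `counts` (a sparse dgCMatrix, genes x cells, dimnames
#'   set) and `features` (the parsed feature table).
#' @export
read_counts_mtx <- function(dir_path) {
  fp <- function(base) {
    for (f in file.path(dir_path, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("missing ", base, " in ", dir_path)
  }
  m <- Matrix::readMM(fp("matrix.mtx"))
  barcodes <- readLines(fp("barcodes.tsv"))
  barcodes <- barcodes[nzchar(barcodes)]
  features <- utils::read.table(fp("features.tsv"), sep = "\t",
                                stringsAsFactors = FALSE)
  if (nrow(features) != nrow(m))
    stop("dimension mismatch: ", nrow(features), " features vs ",
         nrow(m), " matrix rows")
  if (length(barcodes) != ncol(m))
    stop("dimension mismatch: ", length(barcodes), " barcodes vs ",
         ncol(m), " matrix columns")
  dup <- barcodes[duplicated(barcodes)]
  if (length(dup))
    stop("duplicate barcodes: ", paste(unique(dup), collapse = ", "))
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features[[1]], barcodes)
  list(counts = m, features = features)
}

#' Write a cohort to disk in language-neutral formats
#'
#' Emits the 10x triplet (`matrix.mtx`, `barcodes.tsv`, `features.tsv`) plus
#' `adt.csv`, `cell_meta.csv`, `sample_meta.csv`, `gene_positions.tsv` and,
#' when present, `truth_labels.csv`, `contigs_tcr.csv`, `contigs_bcr.csv`
#' and `sim_config.yaml`.
#'
#' @param cohort a `cell_cohort` (extra attributes `truth`, `contigs_tcr`,
#'   `contigs_bcr`, `sim_config` are written if attached).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(Matrix::Matrix(cohort$counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(cohort$counts), file.path(dir, "barcodes.tsv"))
  feats <- data.frame(id = rownames(cohort$counts),
                      name = rownames(cohort$counts),
                      type = "Gene Expression")
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(cohort$cell_meta, file.path(dir, "cell_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$sample_meta, file.path(dir, "sample_meta.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$adt)) {
    adt <- data.frame(marker = rownames(cohort$adt),
                      as.data.frame(as.matrix(cohort$adt)),
                      check.names = FALSE)
    utils::write.csv(adt, file.path(dir, "adt.csv"), row.names = FALSE)
  }
  if (!is.null(cohort$gene_positions))
    utils::write.table(cohort$gene_positions, file.path(dir, "gene_positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- attr(cohort, "truth")
  if (!is.null(truth))
    utils::write.csv(truth$cells, file.path(dir, "truth_labels.csv"), row.names = FALSE)
  for (slot in c("contigs_tcr", "contigs_bcr")) {
    tab <- attr(cohort, slot)
    if (!is.null(tab))
      utils::write.csv(tab, file.path(dir, paste0(slot, ".csv")), row.names = FALSE)
  }
  sc <- attr(cohort, "sim_config")
  if (!is.null(sc))
    yaml::write_yaml(sim_config_to_list(sc), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cell_cohort`.
#' @export
read_cohort <- function(dir) {
  cm <- utils::read.csv(file.path(dir, "cell_meta.csv"), stringsAsFactors = FALSE)
  sm <- utils::read.csv(file.path(dir, "sample_meta.csv"), stringsAsFactors = FALSE)
  mm <- read_counts_mtx(dir)
  adt <- NULL
  adt_path <- file.path(dir, "adt.csv")
  if (file.exists(adt_path)) {
    adf <- utils::read.csv(adt_path, check.names = FALSE, stringsAsFactors = FALSE)
    adt <- as.matrix(adf[, -1, drop = FALSE])
    rownames(adt) <- adf[[1]]
  }
  gp <- NULL
  gp_path <- file.path(dir, "gene_positions.tsv")
  if (file.exists(gp_path))
    gp <- utils::read.table(gp_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  cell_cohort(mm$counts, cm, sm, adt = adt, gene_positions = gp)
}

#' Parse a 10x VDJ filtered contig annotation table
#'
#' One row per assembled contig. `d_gene` may be the literal string "None"
#' (converted to `NA`); chain values are validated against the TCR/BCR chain
#' vocabulary TRA, TRB, IGH, IGK, IGL.
#'
#' @param csv_path path to the contig annotation CSV.
#' @return data.frame of contigs (empty, with the expected columns, for a
#'   header-only file).
#' @export
read_vdj_contigs <- function(csv_path) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("barcode", "chain", "v_gene", "d_gene", "j_gene", "c_gene", "cdr3_nt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("contig table missing required columns: ", paste(miss, collapse = ", "))
  ok_chains <- c("TRA", "TRB", "IGH", "IGK", "IGL")
  bad <- setdiff(unique(tab$chain), ok_chains)
  if (length(bad))
    stop("unknown chain value(s): ", paste(bad, collapse = ", "))
  tab$d_gene[tab$d_gene %in% c("None", "")] <- NA_character_
  if (is.null(tab$umis)) tab$umis <- rep(1L, nrow(tab))
  tab
}
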