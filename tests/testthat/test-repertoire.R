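mk_contig <- function(barcode, chain, v = "V1", d = NA, j = "J1", c_ = "C1",
                      cdr3 = "ATG", umis = 3) {
  data.frame(barcode = barcode, chain = chain, v_gene = v, d_gene = d,
             j_gene = j, c_gene = c_, cdr3_nt = cdr3, umis = umis,
             stringsAsFactors = FALSE)
}

test_that("clonotype calling keys on paired V(D)JC genes + CDR3", {
  contigs <- rbind(
    mk_contig("cell1", "TRA", v = "TRAV1", j = "TRAJ1", c_ = "TRAC", cdr3 = "AAA"),
    mk_contig("cell1", "TRB", v = "TRBV1", d = "TRBD1", j = "TRBJ1", c_ = "TRBC1",
              cdr3 = "CCC"),
    mk_contig("cell2", "TRA", v = "TRAV1", j = "TRAJ1", c_ = "TRAC", cdr3 = "AAA"),
    mk_contig("cell2", "TRB", v = "TRBV1", d = "TRBD1", j = "TRBJ1", c_ = "TRBC1",
              cdr3 = "CCC"),
    mk_contig("cell3", "TRA", v = "TRAV2", j = "TRAJ1", c_ = "TRAC", cdr3 = "AAA"),
    mk_contig("cell3", "TRB", v = "TRBV1", d = "TRBD1", j = "TRBJ1", c_ = "TRBC1",
              cdr3 = "CCC"),
    mk_contig("cell4", "TRA", v = "TRAV9", j = "TRAJ9"))  # unpaired -> excluded
  expect_message(ct <- call_clonotypes(contigs, "TCR"), "excluded")
  expect_equal(nrow(ct), 3)
  id <- setNames(ct$clonotype_id, ct$barcode)
  expect_equal(id[["cell1"]], id[["cell2"]])
  expect_false(id[["cell3"]] == id[["cell1"]])

  # multiple contigs per chain: highest UMI wins, ties by lexicographic CDR3
  multi <- rbind(
    mk_contig("m1", "TRA", v = "TRAV1", cdr3 = "GGG", umis = 9),
    mk_contig("m1", "TRA", v = "TRAV2", cdr3 = "AAA", umis = 2),
    mk_contig("m1", "TRB", v = "TRBV1", cdr3 = "TTT", umis = 3),
    mk_contig("m2", "TRA", v = "TRAV1", cdr3 = "GGG", umis = 9),
    mk_contig("m2", "TRB", v = "TRBV1", cdr3 = "TTT", umis = 3))
  ct2 <- call_clonotypes(multi, "TCR")
  expect_equal(ct2$clonotype_id[1], ct2$clonotype_id[2])

  # BCR pairing: IGH plus either light chain
  bcr <- rbind(
    mk_contig("b1", "IGH", v = "IGHV1", d = "IGHD1", j = "IGHJ1", c_ = "IGHM"),
    mk_contig("b1", "IGK", v = "IGKV1", j = "IGKJ1", c_ = "IGKC"),
    mk_contig("b2", "IGH", v = "IGHV1", d = "IGHD1", j = "IGHJ1", c_ = "IGHM"),
    mk_contig("b2", "IGL", v = "IGLV1", j = "IGLJ1", c_ = "IGLC"),
    mk_contig("b3", "IGK", v = "IGKV1", j = "IGKJ1", c_ = "IGKC"))
  expect_message(cb <- call_clonotypes(bcr, "BCR"), "excluded")
  expect_setequal(cb$barcode, c("b1", "b2"))
  expect_false(cb$clonotype_id[1] == cb$clonotype_id[2]) # different light chains
})

test_that("planted clonal partition is recovered exactly", {
  sim <- small_sim()
  contigs <- attr(sim$cohort, "contigs_tcr")
  truth <- attr(contigs, "clonotype_truth")
  ct <- call_clonotypes(contigs, "TCR")
  called <- setNames(ct$clonotype_id, ct$barcode)
  expect_setequal(names(called), names(truth))
  # partition identity: same cells together iff same truth clone
  tr <- truth[names(called)]
  cross <- table(tr, called)
  expect_true(all(rowSums(cross > 0) == 1))
  expect_true(all(colSums(cross > 0) == 1))
})

test_that("clone-size classes reproduce the stated bins at all boundaries", {
  sizes <- c(1, 2, 5, 6, 10, 11, 20, 21)
  expected <- c("Single", "Small", "Small", "Medium", "Medium", "Large",
                "Large", "Hyperexpanded")
  tab <- data.frame(
    barcode = sprintf("c%03d", seq_len(sum(sizes))),
    clonotype_id = rep(sprintf("ct%02d", seq_along(sizes)), times = sizes),
    stringsAsFactors = FALSE)
  out <- classify_clone_sizes(tab)
  got <- out$size_class[match(sprintf("ct%02d", seq_along(sizes)),
                              out$clonotype_id)]
  expect_equal(got, expected)
  expect_equal(out$clone_size[match(sprintf("ct%02d", seq_along(sizes)),
                                    out$clonotype_id)], sizes)
  # histogram equals a brute-force binning oracle on random clone sizes
  set.seed(23)
  rnd_sizes <- sample(1:30, 40, replace = TRUE)
  tab2 <- data.frame(
    barcode = sprintf("r%04d", seq_len(sum(rnd_sizes))),
    clonotype_id = rep(sprintf("rc%02d", seq_along(rnd_sizes)), times = rnd_sizes),
    stringsAsFactors = FALSE)
  out2 <- classify_clone_sizes(tab2)
  oracle <- function(n) if (n <= 1) "Single" else if (n <= 5) "Small" else
    if (n <= 10) "Medium" else if (n <= 20) "Large" else "Hyperexpanded"
  expect_equal(out2$size_class, vapply(out2$clone_size, oracle, character(1)))
  # strictly increasing bounds are enforced
  expect_error(clone_size_bins(c(Single = 1, Small = 1, Hyper = Inf)),
               "strictly increasing")
})

test_that("relative clone size uses the (sample, compartment) denominator", {
  tab <- data.frame(
    barcode = sprintf("c%02d", 1:10),
    clonotype_id = c(rep("A", 3), rep("B", 2), rep("C", 3), "D", "E"),
    stringsAsFactors = FALSE)
  comp <- c(rep("CD4T", 5), rep("CD8T", 5))
  samp <- rep("S1", 10)
  out <- classify_clone_sizes(tab, compartment = comp, sample_ids = samp)
  expect_equal(out$relative_clone_size[1], 3 / 5)  # clone A in 5 CD4 cells
  expect_equal(out$relative_clone_size[6], 3 / 5)  # clone C in 5 CD8 cells
  # clone sizes within a compartment sum to the compartment's paired cells
  expect_equal(sum(unique(out[out$compartment == "CD4T",
                              c("clonotype_id", "clone_size")])$clone_size), 5)
  expect_true(all(out$relative_clone_size > 0 & out$relative_clone_size <= 1))
})

test_that("functional scores equal gene-set means and separate planted states", {
  norm <- matrix(0, 19, 3,
                 dimnames = list(c(functional_gene_sets()$regulatory,
                                   functional_gene_sets()$cytotoxic),
                                 c("c1", "c2", "c3")))
  norm[1:11, 2] <- 2    # regulatory genes on in cell 2
  fs <- functional_scores(norm)
  expect_equal(fs$regulatory, c(0, 2, 0))
  expect_equal(fs$cytotoxic, c(0, 0, 0))
  # brute-force mean oracle on random values
  set.seed(24)
  norm[] <- runif(length(norm))
  fs2 <- functional_scores(norm)
  expect_equal(fs2$cytotoxic[1],
               mean(norm[functional_gene_sets()$cytotoxic, 1]))
  # planted Tregs outscore effector CD8 cells on the regulatory program
  sp <- small_sim_prepped()
  sc <- score_gene_set(sp$norm, functional_gene_sets()$regulatory)
  treg <- sc[sp$truth$subtype == "CD4_Treg"]
  teff <- sc[sp$truth$subtype == "CD8_TEM"]
  expect_gte(mean(outer(treg, teff, ">")), 0.99)
})
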