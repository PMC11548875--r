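make_positions <- function(genes, chromosome = "chr1") {
  data.frame(gene_id = genes, chromosome = chromosome,
             start = seq_along(genes) * 1000,
             end = seq_along(genes) * 1000 + 500, stringsAsFactors = FALSE)
}

test_that("build_genomic_order sorts by chromosome then start and drops unknowns", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    chromosome = c("chr2", "chr1", "chr1"),
                    start = c(50, 200, 100), end = c(60, 210, 110),
                    stringsAsFactors = FALSE)
  go <- build_genomic_order(tab, c("a", "b", "c"))
  expect_equal(go$gene_id, c("c", "b", "a"))
  # gene without a position is dropped with a message
  expect_message(go2 <- build_genomic_order(tab, c("a", "b", "c", "d")),
                 "without genomic position")
  expect_equal(go2$gene_id, c("c", "b", "a"))
  # permutation invariance of the input table
  shuffled <- tab[c(3, 1, 2), ]
  expect_equal(build_genomic_order(shuffled, c("a", "b", "c")), go)
  expect_error(build_genomic_order(tab, c("x", "y")), "no overlap")
})

test_that("cells identical to the reference mean give a null signal", {
  genes <- sprintf("g%03d", 1:120)
  norm <- matrix(rep(runif(120, 0.5, 2), 10), 120, 10,
                 dimnames = list(genes, paste0("c", 1:10)))
  prof <- infer_cnv_signal(norm, rep(c(TRUE, FALSE), 5),
                           make_positions(genes),
                           cnv_params(window_genes = 11, denoise = FALSE),
                           counts = norm)
  expect_lt(max(abs(prof$signal)), 1e-10)
})

test_that("a planted gain raises the smoothed signal inside the event", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:300)
  base <- runif(300, 1, 2)
  ref <- matrix(rep(base, 30), 300, 30) + rnorm(9000, 0, 0.05)
  qry <- matrix(rep(base, 10), 300, 10) + rnorm(3000, 0, 0.05)
  qry[100:200, ] <- qry[100:200, ] + 0.4
  norm <- cbind(ref, qry)
  dimnames(norm) <- list(genes, paste0("c", 1:40))
  prof <- infer_cnv_signal(norm, c(rep(TRUE, 30), rep(FALSE, 10)),
                           make_positions(genes),
                           cnv_params(window_genes = 21, denoise = FALSE),
                           counts = norm)
  sig_q <- prof$signal[, 31:40]
  inside <- prof$gene_order$gene_id %in% genes[110:190]
  outside <- prof$gene_order$gene_id %in% genes[c(1:80, 220:300)]
  expect_gt(mean(sig_q[inside, ]), mean(sig_q[outside, ]))
  expect_gt(mean(sig_q[inside, ]) - mean(sig_q[outside, ]), 0.2)

  # reference mean profile is ~0 per window after two-pass centering
  ref_mean <- rowMeans(prof$signal[, 1:30])
  expect_lt(max(abs(ref_mean)), 1e-8)
})

test_that("widening the smoothing window cannot increase signal variance", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:400)
  norm <- matrix(runif(400 * 25, 0, 3), 400, 25,
                 dimnames = list(genes, paste0("c", 1:25)))
  p1 <- infer_cnv_signal(norm, rep(c(TRUE, FALSE), c(15, 10)),
                         make_positions(genes),
                         cnv_params(window_genes = 25, denoise = FALSE),
                         counts = norm)
  p2 <- infer_cnv_signal(norm, rep(c(TRUE, FALSE), c(15, 10)),
                         make_positions(genes),
                         cnv_params(window_genes = 51, denoise = FALSE),
                         counts = norm)
  expect_lte(var(as.vector(p2$signal)), var(as.vector(p1$signal)))
})

test_that("summarize_cnv_cells matches independent sd/cor oracles", {
  set.seed(9)
  sig <- matrix(rnorm(200 * 30), 200, 30,
                dimnames = list(NULL, sprintf("c%02d", 1:30)))
  sig[, 1:3] <- sig[, 1:3] * 4      # high-variance cells
  smry <- summarize_cnv_cells(sig, cnv_params(top_cell_fraction = 0.1))
  # two-pass variance oracle
  expect_lt(max(abs(smry$sd - apply(sig, 2, sd))), 1e-12)
  top <- order(-apply(sig, 2, sd))[1:3]
  expect_setequal(attr(smry, "top_cells"), top)
  tm <- rowMeans(sig[, top])
  expect_lt(max(abs(smry$cor - as.vector(cor(sig, tm)))), 1e-12)
  # a flat cell has sd 0 and NA correlation
  sig2 <- cbind(sig, flat = rep(1, 200))
  smry2 <- summarize_cnv_cells(sig2, cnv_params(top_cell_fraction = 0.1))
  expect_equal(smry2$sd[31], 0)
  expect_true(is.na(smry2$cor[31]))
  expect_error(summarize_cnv_cells(sig[, 1:10]), "fewer than 20")
  # scaling all signals by c > 0 scales sd and keeps cor
  sc <- summarize_cnv_cells(sig * 2.5, cnv_params(top_cell_fraction = 0.1))
  expect_equal(sc$sd, smry$sd * 2.5)
  expect_equal(sc$cor, smry$cor)
})

test_that("threshold calling implements sd > 0.03 OR cor > 0.3 strictly", {
  smry <- data.frame(barcode = paste0("c", 1:5),
                     sd = c(0.05, 0.01, 0.031, 0.03, 0.01),
                     cor = c(0.0, 0.1, 0.0, 0.3, NA))
  call <- call_malignant_threshold(smry)
  expect_equal(unname(call), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # candidate restriction: non-candidates never called
  call2 <- call_malignant_threshold(smry, candidate_mask = c(TRUE, TRUE, FALSE,
                                                             TRUE, TRUE))
  expect_false(call2[3])
})

test_that("the mixture caller separates bimodal variance and is deterministic", {
  set.seed(10)
  lo <- matrix(rnorm(100 * 60, sd = 0.02), 100, 60)
  hi <- matrix(rnorm(100 * 40, sd = 0.2), 100, 40)
  sig <- cbind(lo, hi)
  colnames(sig) <- sprintf("c%03d", 1:100)
  call <- aneuploid_cluster_call(sig)
  truth <- c(rep(FALSE, 60), rep(TRUE, 40))
  expect_gte(mean(call == truth), 0.9)
  expect_identical(call, aneuploid_cluster_call(sig))
  # identical cells -> degenerate -> all diploid with a warning
  flat <- matrix(rep(rnorm(50), 30), 50, 30,
                 dimnames = list(NULL, paste0("f", 1:30)))
  expect_warning(c2 <- aneuploid_cluster_call(flat), "diploid")
  expect_false(any(c2))
})

test_that("consensus_union is logical OR over a shared universe", {
  a <- c(x = TRUE, y = FALSE, z = FALSE)
  b <- c(x = FALSE, y = FALSE, z = TRUE)
  expect_equal(consensus_union(a, b), c(x = TRUE, y = FALSE, z = TRUE))
  expect_error(consensus_union(a, b[1:2]), "differ in size")
  expect_error(consensus_union(a, c(q = TRUE, y = TRUE, z = FALSE)),
               "do not match")
  # consensus sensitivity >= each individual sensitivity by construction
  set.seed(2)
  truth <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  ca <- truth & runif(200) < 0.8
  cb <- truth & runif(200) < 0.7
  cons <- consensus_union(ca, cb)
  expect_gte(mean(cons[truth]), max(mean(ca[truth]), mean(cb[truth])))
})

test_that("malignant calling is invariant to cell-column permutation", {
  sp <- small_sim_prepped()
  go <- build_genomic_order(sp$kept$gene_positions, rownames(sp$kept$counts))
  cm <- sp$kept$cell_meta
  sm <- sp$kept$sample_meta
  ns <- sm$sample_id[is.na(sm$recist)]
  pool <- cm$barcode[cm$lineage == "Epithelial" & cm$sample_id %in% ns]
  ts <- setdiff(unique(cm$sample_id), ns)[1]
  res <- call_malignant_cells(sp$norm, sp$kept$counts, cm, go,
                              normal_pool = pool, tumor_samples = ts)
  set.seed(4)
  perm <- sample(ncol(sp$norm))
  res_p <- call_malignant_cells(sp$norm[, perm], sp$kept$counts[, perm],
                                cm[perm, ], go, normal_pool = pool,
                                tumor_samples = ts)
  res_p <- res_p[match(res$barcode, res_p$barcode), ]
  expect_equal(res_p$sd, res$sd)
  expect_equal(res_p$threshold_call, res$threshold_call, ignore_attr = TRUE)
})
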