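test_that("rank-sum p-values match exact enumeration and the normal approximation", {
  # closed-case oracle: A=[1,2,3] vs B=[4,5,6] -> 2/20 arrangements as extreme
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # independent enumeration oracle on random small samples (with ties)
  set.seed(12)
  for (i in 1:5) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 6, replace = TRUE)
    expect_equal(rank_sum_test(x, y), enumerate_rank_sum_p(x, y))
  }
  # large tie-free samples agree with the uncorrected normal approximation
  x <- rnorm(30); y <- rnorm(25) + 0.5
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(rank_sum_test(x, y), ref, tolerance = 1e-12)
})

test_that("wilcoxon_deg applies the four-way filter and is antisymmetric", {
  set.seed(13)
  n <- 120
  norm <- matrix(rnorm(50 * 2 * n, mean = 1.2, sd = 0.3), 50, 2 * n,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("c%03d", 1:(2 * n))))
  norm[norm < 0] <- 0
  up_genes <- sprintf("g%02d", 1:5)
  norm[up_genes, 1:n] <- norm[up_genes, 1:n] + 0.6
  a <- colnames(norm)[1:n]; b <- colnames(norm)[(n + 1):(2 * n)]
  res <- wilcoxon_deg(norm, a, b)
  expect_setequal(res$up, up_genes)
  expect_equal(res$down, character(0))
  expect_true(all(res$table$adj_p >= res$table$p))
  # swapping groups negates logfc and swaps up/down
  res2 <- wilcoxon_deg(norm, b, a)
  expect_setequal(res2$down, res$up)
  expect_setequal(res2$up, res$down)
  common <- intersect(res$table$gene, res2$table$gene)
  expect_equal(res$table$logfc[match(common, res$table$gene)],
               -res2$table$logfc[match(common, res2$table$gene)])
  # identical groups produce no candidate genes
  norm_dup <- cbind(norm, norm)
  colnames(norm_dup) <- c(colnames(norm), paste0(colnames(norm), ".1"))
  res3 <- wilcoxon_deg(norm_dup, colnames(norm),
                       paste0(colnames(norm), ".1"))
  expect_equal(nrow(res3$table), 0)
  expect_error(wilcoxon_deg(norm, a, a[1:10]), "overlap")
  expect_error(wilcoxon_deg(norm, a[1:2], b), ">= 3 cells")
})

test_that("INT/UNION signatures follow set algebra", {
  mk <- function(up, down) list(up = up, down = down)
  tabs <- list(mk(c("a", "b"), c("q")), mk(c("b", "c"), c("q", "r")),
               mk(c("b"), c("q", "s")))
  sig <- build_int_union(tabs)
  expect_equal(sig$INT.up$genes, "b")
  expect_setequal(sig$UNION.up$genes, c("a", "b", "c"))
  expect_equal(sig$INT.down$genes, "q")
  expect_setequal(sig$UNION.down$genes, c("q", "r", "s"))
  # identical tables -> INT equals UNION
  same <- list(tabs[[1]], tabs[[1]], tabs[[1]])
  s2 <- build_int_union(same)
  expect_setequal(s2$INT.up$genes, s2$UNION.up$genes)
  expect_error(build_int_union(tabs[1:2]), "three")
  # random toy sets against a brute-force oracle
  set.seed(14)
  pool <- letters
  rnd <- replicate(3, mk(sample(pool, 8), sample(pool, 8)), simplify = FALSE)
  s3 <- build_int_union(rnd)
  expect_setequal(s3$UNION.up$genes,
                  unique(c(rnd[[1]]$up, rnd[[2]]$up, rnd[[3]]$up)))
  expect_setequal(s3$INT.up$genes,
                  pool[vapply(pool, function(g)
                    all(vapply(rnd, function(t) g %in% t$up, logical(1))),
                    logical(1))])
})

test_that("NMF reconstructs exactly representable input and decreases error", {
  set.seed(15)
  u <- runif(40, 0.5, 2); v <- runif(25, 0.5, 2)
  m <- u %*% t(v)
  dimnames(m) <- list(paste0("g", 1:40), paste0("c", 1:25))
  fit <- fit_nmf(m, rank = 1, max_iter = 500, tol = 1e-12, seed = 2)
  expect_lt(fit$error, 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  # monotone error trace on random data
  r <- matrix(runif(60 * 30), 60, 30,
              dimnames = list(paste0("g", 1:60), paste0("c", 1:30)))
  fit2 <- fit_nmf(r, rank = 5, max_iter = 80, tol = 0, seed = 3)
  expect_true(all(diff(fit2$error_trace) <= 1e-10))
  expect_error(fit_nmf(r - 1, rank = 2), "non-negative")
})

test_that("NMF recovers planted block structure at matching rank", {
  set.seed(16)
  blocks <- 4; per <- 30; cells_per <- 25
  W0 <- matrix(0.02, blocks * per, blocks)
  for (b in seq_len(blocks)) W0[((b - 1) * per + 1):(b * per), b] <- 1
  H0 <- matrix(0.02, blocks, blocks * cells_per)
  for (b in seq_len(blocks)) H0[b, ((b - 1) * cells_per + 1):(b * cells_per)] <- 1
  m <- matrix(rpois(length(W0 %*% H0), 30 * (W0 %*% H0)), nrow(W0))
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))), paste0("c", seq_len(ncol(m))))
  fit <- fit_nmf(m, rank = 4, max_iter = 300, tol = 1e-9, seed = 4)
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  best <- vapply(seq_len(blocks), function(b)
    max(vapply(seq_len(4), function(f) cos_sim(W0[, b], fit$W[, f]),
               numeric(1))), numeric(1))
  expect_true(all(best >= 0.9))
})

test_that("factor-to-group shares behave at the symmetry and exclusivity extremes", {
  W <- matrix(runif(40 * 3), 40, 3,
              dimnames = list(paste0("g", 1:40), paste0("factor", 1:3)))
  groups <- rep(c("PR", "SD", "PD"), each = 10)
  # uniform loadings -> all shares exactly 1/3, nothing assigned
  H_flat <- matrix(1, 3, 30, dimnames = list(colnames(W), NULL))
  model <- structure(list(W = W, H = H_flat), class = "nmf_model")
  out <- derive_nmf_programs(model, groups)
  expect_true(all(abs(out$shares - 1 / 3) < 1e-12))
  expect_true(all(is.na(out$assignment)))
  expect_true(all(abs(rowSums(out$shares) - 1) < 1e-9))
  # loading confined to PR cells -> share 1, assigned to PR
  H_pr <- H_flat; H_pr[1, ] <- 0; H_pr[1, groups == "PR"] <- 5
  model2 <- structure(list(W = W, H = H_pr), class = "nmf_model")
  out2 <- derive_nmf_programs(model2, groups, top_genes_per_factor = 10)
  expect_equal(unname(out2$assignment[1]), "PR")
  expect_equal(out2$shares[1, "PR"], 1)
  top10 <- rownames(W)[order(-W[, 1])[1:10]]
  expect_setequal(out2$programs$NMF.PR$genes, top10)
  expect_error(derive_nmf_programs(model, rep("PR", 30)), NA)
})

test_that("top-coefficient modules equal a sort-based oracle", {
  co1 <- setNames(seq(200, 1), sprintf("g%03d", 1:200))  # strictly decreasing
  mods <- refine_top_gene_modules(list(m1 = co1), c(m1 = "PD"), top_n = 100)
  expect_equal(mods$module.PD$genes, sprintf("g%03d", 1:100))
  # two identical modules in one group -> union equals either set
  mods2 <- refine_top_gene_modules(list(m1 = co1, m2 = co1),
                                   c(m1 = "PD", m2 = "PD"), top_n = 100)
  expect_setequal(mods2$module.PD$genes, mods$module.PD$genes)
  # random coefficients vs oracle
  set.seed(17)
  co2 <- setNames(runif(150), sprintf("r%03d", 1:150))
  mods3 <- refine_top_gene_modules(list(a = co2), c(a = "PR"), top_n = 40)
  expect_setequal(mods3$module.PR$genes,
                  names(sort(co2, decreasing = TRUE))[1:40])
  expect_warning(refine_top_gene_modules(list(a = co2[1:10]), c(a = "PR")),
                 "fewer than")
})

test_that("enrichment odds ratios match the corrected cross-product and Fisher tails", {
  # [[10,0],[0,10]]: corrected OR = (10.5*10.5)/(0.5*0.5) = 441
  prog <- rep(c("p1", "p2"), each = 10)
  grp <- rep(c("PR", "PD"), each = 10)
  res <- enrichment_odds_ratio(prog, grp)
  r11 <- res[res$program == "p1" & res$group == "PR", ]
  expect_equal(r11$odds_ratio, 441)
  expect_equal(r11$p, 2 / choose(20, 10), tolerance = 1e-10)
  # [[5,5],[5,5]] -> OR 1, p 1
  res2 <- enrichment_odds_ratio(rep(c("p1", "p2"), 10), rep(c("PR", "PD"), each = 10))
  expect_equal(res2$odds_ratio[1], 1)
  expect_equal(res2$p[1], 1)
  expect_error(enrichment_odds_ratio(prog, rep("PR", 20)), "two groups")
  # Fisher p equals stats::fisher.test on random small tables
  set.seed(18)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(sciri:::fisher_exact_p(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
  # OR invariant under simultaneous row and column swap
  tabx <- matrix(c(8, 3, 2, 9), 2)
  or_of <- function(t) (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  expect_equal(or_of(tabx), or_of(tabx[2:1, 2:1]))
})

test_that("PC signatures are orthonormal, deterministic and recover a planted axis", {
  set.seed(19)
  n_genes <- 120; n_cells <- 200
  scaled <- matrix(rnorm(n_genes * n_cells), n_genes, n_cells,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%03d", 1:n_cells)))
  axis_genes <- sprintf("g%03d", 1:30)
  latent <- rnorm(n_cells, sd = 4)
  scaled[axis_genes, ] <- scaled[axis_genes, ] + outer(rep(1, 30), latent)
  ps <- pca_signatures(scaled, n_pcs = 5, top_genes = 30)
  expect_gte(length(intersect(ps$signatures$PC1.pos$genes, axis_genes)), 27)
  # orthonormal loadings
  g <- crossprod(ps$rotation)
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-8)
  # deterministic under cell permutation (sign convention)
  perm <- sample(n_cells)
  ps2 <- pca_signatures(scaled[, perm], n_pcs = 5, top_genes = 30)
  expect_equal(ps$signatures$PC1.pos$genes, ps2$signatures$PC1.pos$genes)
  expect_equal(ps$signatures$PC2.neg$genes, ps2$signatures$PC2.neg$genes)
  expect_error(pca_signatures(scaled[1:40, ], top_genes = 30), "at least 60")
})

test_that("per-sample signature scores are max-normalized means", {
  set.seed(20)
  norm <- matrix(runif(30 * 60, 0, 3), 30, 60,
                 dimnames = list(paste0("g", 1:30), paste0("c", 1:60)))
  samples <- rep(c("S1", "S2", "S3"), each = 20)
  mal <- rep(c(TRUE, FALSE), 30)
  sig <- gene_signature("test", paste0("g", 1:5))
  sc <- score_signature_per_sample(norm, sig, mal, samples)
  # brute-force double loop oracle
  raw <- sapply(c("S1", "S2", "S3"), function(s) {
    cells <- which(samples == s & mal)
    mean(sapply(cells, function(cl) mean(norm[paste0("g", 1:5), cl])))
  })
  expect_equal(unname(sc), unname(raw / max(raw)), tolerance = 1e-12)
  # single sample scores 1; doubling expression changes nothing
  one <- score_signature_per_sample(norm, sig, mal, rep("S1", 60))
  expect_equal(unname(one), 1)
  expect_equal(score_signature_per_sample(norm * 2, sig, mal, samples), sc)
  # sample without malignant cells -> NA
  mal2 <- mal; mal2[samples == "S2"] <- FALSE
  sc2 <- score_signature_per_sample(norm, sig, mal2, samples)
  expect_true(is.na(sc2["S2"]))
})
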