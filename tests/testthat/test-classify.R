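test_that("Ro/e equals observed over chi-square expected counts", {
  r1 <- compute_roe(matrix(10, 2, 2))
  expect_true(all(r1$roe == 1))
  r2 <- compute_roe(matrix(c(20, 0, 0, 20), 2))
  expect_equal(unname(diag(r2$roe)), c(2, 2))
  expect_equal(r2$roe[1, 2], 0)
  # brute-force E = row * col / N oracle on a random 3x4 table
  set.seed(25)
  m <- matrix(rpois(12, 20), 3, 4)
  r3 <- compute_roe(m)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_lt(max(abs(r3$roe - m / e)), 1e-12)
  expect_equal(sum(r3$expected), sum(m))
  # invariant to scaling all counts by a positive integer
  r4 <- compute_roe(m * 3)
  expect_equal(r4$roe, r3$roe)
  expect_error(compute_roe(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  # empty row -> undefined Ro/e flagged as NA
  m0 <- rbind(m, 0)
  expect_true(all(is.na(compute_roe(m0)$roe[4, ])))
})

test_that("proportion t-tests match closed forms and conventions", {
  # mirror-image samples: equal means and variances -> t = 0, p = 1
  out <- compare_proportions(c(0.1, 0.2, 0.2, 0.1), c("a", "a", "b", "b"))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # Welch p equals the closed form with Welch-Satterthwaite df on 3v3
  x <- c(0.12, 0.18, 0.25); y <- c(0.30, 0.42, 0.35)
  got <- compare_proportions(c(x, y), rep(c("a", "b"), each = 3))
  sx <- var(x) / 3; sy <- var(y) / 3
  tstat <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / 2 + sy^2 / 2)
  expect_equal(got$t, tstat, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  # pooled Student variant is selectable
  got2 <- compare_proportions(c(x, y), rep(c("a", "b"), each = 3),
                              var_equal = TRUE)
  expect_equal(got2$p, t.test(x, y, var.equal = TRUE)$p.value)
  # degenerate zero-variance groups
  z <- compare_proportions(c(0.2, 0.2, 0.2, 0.2), rep(c("a", "b"), each = 2))
  expect_equal(z$p, 1)
  expect_error(compare_proportions(c(0.1, 0.2), c("a", "b")), ">= 2 samples")
})

test_that("planted Treg excess in non-responders is detected in >= 8/10 seeds", {
  # default cohort composition (14 samples, default effect sizes); the gene
  # space is irrelevant for composition tests, so a small genome keeps this
  # replicate loop fast
  hits <- 0
  for (seed in 1:10) {
    cfg <- sim_config(cells_per_sample = 600, n_normal_samples = 0,
                      n_genes = 200, cnv_events = list(), seed = seed)
    sim <- simulate_cohort(cfg)
    cm <- sim$cohort$cell_meta
    props <- subtype_proportions(cm, "immune")
    sm <- sim$cohort$sample_meta
    resp <- sm$response[match(colnames(props), sm$sample_id)]
    res <- compare_proportions(props["CD4_Treg", ], resp)
    # direction: overrepresented in the non-responder group
    dir_ok <- (res$mean_difference < 0) == (resp[1] == "responder")
    hits <- hits + (res$p < 0.05 && dir_ok)
  }
  expect_gte(hits, 8)
})

test_that("univariate regression matches its F = t^2 identity and calibration", {
  set.seed(26)
  y <- rep(c(0, 1), each = 7)
  x <- rnorm(14)
  u <- univariate_regression(x, y)
  fit <- summary(lm(y ~ x))
  expect_equal(u$f_statistic, fit$coefficients[2, "t value"]^2,
               tolerance = 1e-10)
  expect_equal(u$p, fit$coefficients[2, "Pr(>|t|)"], tolerance = 1e-10)
  # predictor identical to response -> perfect fit
  uid <- suppressWarnings(univariate_regression(as.numeric(y), y))
  expect_lt(uid$p, 1e-12)
  # constant predictor flagged
  uc <- univariate_regression(rep(2, 14), y)
  expect_equal(uc$flag, "constant")
  expect_true(is.na(uc$p))
  # factor (clinical) predictors are dummy-coded
  uf <- univariate_regression(factor(rep(c("mLN", "Lung"), 7)), y)
  expect_true(is.finite(uf$p))
  # permuted-response null p-values are uniform
  ps <- suppressWarnings(replicate(300, univariate_regression(x, sample(y))$p))
  # permutations of a 14-sample response repeat, so p-values tie; the KS
  # statistic is still a valid uniformity check
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the combinatorial index respects orientation and degeneracies", {
  fm <- cbind(f1 = c(0.2, 0.8, 0.4, 1.0, 0.1, 0.9),
              f2 = c(0.1, 0.9, 0.5, 0.8, 0.2, 1.0),
              const = rep(0.5, 6))
  rownames(fm) <- paste0("S", 1:6)
  labels <- c(0, 1, 0, 1, 0, 1)
  ori <- c(f1 = 1, f2 = 1, const = 1)
  # identical features -> index is 2x the feature, AUC unchanged
  idx <- build_combinatorial_index(fm, c("f1", "f1"), ori)
  expect_equal(unname(idx), unname(2 * fm[, "f1"] / max(fm[, "f1"])))
  expect_equal(roc_auc(idx, labels)$auc, roc_auc(fm[, "f1"], labels)$auc)
  # one constant feature -> AUC equals the other feature's
  idx2 <- build_combinatorial_index(fm, c("f1", "const"), ori)
  expect_equal(roc_auc(idx2, labels)$auc, roc_auc(fm[, "f1"], labels)$auc)
  # responder-associated features enter as (1 - value)
  idx3 <- build_combinatorial_index(fm, c("f1", "f2"), c(f1 = 1, f2 = -1))
  expect_equal(unname(idx3),
               unname(fm[, "f1"] / max(fm[, "f1"]) +
                        (1 - fm[, "f2"] / max(fm[, "f2"]))))
})

test_that("AUC equals the brute-force pairwise U statistic", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  set.seed(27)
  for (i in 1:5) {
    s <- sample(1:8, 12, replace = TRUE)   # plenty of ties
    l <- rep(c(0, 1), each = 6)
    raw <- brute_force_auc(s, l)
    got <- roc_auc(s, l)
    expect_equal(got$auc, max(raw, 1 - raw), tolerance = 1e-12)
    # orientation: auc(s) + auc(-s) = 1 before flipping
    flipped <- roc_auc(-s, l)
    expect_equal(got$auc, flipped$auc, tolerance = 1e-12)
    expect_equal(got$orientation * flipped$orientation,
                 if (abs(raw - 0.5) < 1e-12) 1 else -1)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("the ROC screen ranks combinations with BH-adjusted p-values", {
  set.seed(28)
  n <- 14
  labels <- rep(c(0, 1), c(5, 9))
  fm <- cbind(strong = labels + rnorm(n, 0, 0.3),
              weak = labels + rnorm(n, 0, 1.5),
              noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(fm) <- sprintf("S%02d", 1:n)
  res <- screen_combinations(fm, labels, top_k = 3)
  expect_true(all(c("single", "pair") %in% res$type))
  expect_equal(nrow(res[res$type == "pair", ]), choose(3, 2))
  # ranked by AUC then q
  expect_true(all(diff(res$auc) <= 1e-12))
  # BH equals the step-up oracle over all evaluated combinations
  expect_equal(res$q, bh_step_up(res$p))
  # q monotone in sorted-p order after cummin enforcement
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  # single candidate: q = p
  res1 <- screen_combinations(fm[, "strong", drop = FALSE], labels,
                              candidate_features = "strong", top_k = 3)
  expect_equal(res1$q, res1$p)
})

test_that("combining two independently informative features rarely hurts", {
  set.seed(29)
  wins <- 0; reps <- 100
  for (i in seq_len(reps)) {
    labels <- rep(c(0, 1), c(5, 9))
    fm <- cbind(a = labels + rnorm(14, 0, 0.35),
                b = labels + rnorm(14, 0, 0.35))
    fm <- apply(fm, 2, function(v) (v - min(v)) / (max(v) - min(v)))
    rownames(fm) <- sprintf("S%02d", 1:14)
    idx <- build_combinatorial_index(fm, c("a", "b"), c(a = 1, b = 1))
    auc_pair <- roc_auc(idx, labels)$auc
    auc_single <- max(roc_auc(fm[, "a"], labels)$auc,
                      roc_auc(fm[, "b"], labels)$auc)
    wins <- wins + (auc_pair >= auc_single - 1e-12)
  }
  expect_gte(wins / reps, 0.9)
})
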