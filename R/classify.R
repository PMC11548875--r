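#' Ro/e: observed over expected cell-type composition
#'
#' Expected counts come from the chi-square independence model
#' (E = row total x column total / grand total, as returned by the
#' chi-square test); Ro/e = O/E. Cells with zero expectation (empty row or
#' column) are undefined and returned as NA.
#'
#' @param counts_table non-negative integer matrix (cell types x samples or
#'   groups).
#' @return list of class `roe_table`: `observed`, `expected`, `roe`.
#' @export
compute_roe <- function(counts_table) {
  m <- as.matrix(counts_table)
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) <= 0) stop("grand total must be positive")
  expected <- suppressWarnings(stats::chisq.test(m)$expected)
  roe <- m / expected
  roe[expected == 0] <- NA_real_
  structure(list(observed = m, expected = expected, roe = roe),
            class = "roe_table")
}

#' Two-sample t-test on per-sample proportions
#'
#' Welch by default (pooled-variance Student variant selectable). When both
#' groups have zero variance and equal means, p = 1 by convention.
#'
#' @param proportions per-sample values.
#' @param groups two-level factor/character aligned with `proportions`.
#' @param var_equal pooled-variance Student's t when TRUE.
#' @return list (mean_difference, t, p) where mean_difference is
#'   group1 - group2 in the order of `unique(groups)`.
#' @export
compare_proportions <- function(proportions, groups, var_equal = FALSE) {
  g <- unique(as.character(groups))
  if (length(g) != 2) stop("exactly two groups are required")
  a <- proportions[groups == g[1]]; b <- proportions[groups == g[2]]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 samples per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(mean_difference = mean(a) - mean(b),
                t = if (mean(a) == mean(b)) 0 else Inf,
                p = if (mean(a) == mean(b)) 1 else 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(mean_difference = mean(a) - mean(b), t = unname(ht$statistic),
       p = ht$p.value)
}

#' Per-sample subtype proportions
#'
#' @param cell_meta per-cell table with `sample_id` and `subtype`.
#' @param denominator "lineage" (within the subtype's coarse lineage, e.g.
#'   T subtypes within total CD4+CD8 cells), "immune" (within all immune
#'   cells) or "total".
#' @param lineage per-cell coarse lineage (needed for "lineage"/"immune").
#' @return matrix subtypes x samples of proportions.
#' @export
subtype_proportions <- function(cell_meta, denominator = c("immune", "lineage", "total"),
                                lineage = cell_meta$lineage) {
  denominator <- match.arg(denominator)
  keep <- rep(TRUE, nrow(cell_meta))
  if (denominator %in% c("immune", "lineage"))
    keep <- lineage %in% c("TNK", "B", "Myeloid", "Mast")
  tab <- table(cell_meta$subtype[keep], cell_meta$sample_id[keep])
  if (denominator == "lineage") {
    lin_of <- tapply(lineage[keep], cell_meta$subtype[keep], function(x) x[1])
    out <- tab
    for (l in unique(lin_of)) {
      rows <- names(lin_of)[lin_of == l]
      tot <- colSums(tab[rows, , drop = FALSE])
      out[rows, ] <- sweep(tab[rows, , drop = FALSE], 2, pmax(tot, 1), "/")
    }
    return(as.matrix(unclass(out)))
  }
  sweep(as.matrix(unclass(tab)), 2, pmax(colSums(tab), 1), "/")
}

#' Univariate regression of response on one feature
#'
#' Ordinary least squares of the 0/1 response (1 = non-responder) on a
#' single predictor; significance from the F-test of the predictor
#' (identical to the squared t-test of its coefficient).
#'
#' @param feature per-sample predictor (numeric, or factor for clinical
#'   variables, dummy-coded by `lm`).
#' @param response01 0/1 response aligned with `feature`.
#' @return list (coefficient, p, f_statistic); a constant predictor yields
#'   NA with `flag = "constant"`.
#' @export
univariate_regression <- function(feature, response01) {
  if (is.character(feature)) feature <- factor(feature)
  if ((is.numeric(feature) && stats::sd(feature) == 0) ||
      (is.factor(feature) && nlevels(droplevels(feature)) < 2))
    return(list(coefficient = NA_real_, p = NA_real_, f_statistic = NA_real_,
                flag = "constant"))
  fit <- stats::lm(response01 ~ feature)
  an <- stats::anova(fit)
  list(coefficient = unname(stats::coef(fit)[2]),
       p = an[["Pr(>F)"]][1], f_statistic = an[["F value"]][1], flag = "ok")
}

#' Combinatorial tumor+immune index
#'
#' Features are max-normalized to [0, 1] across samples; orientation signs
#' come from the univariate coefficient signs (with response coded 1 =
#' non-responder). A non-responder-associated feature enters as its value; a
#' responder-associated feature enters as (1 - value), so that a higher
#' index is more non-responder-like. The index is the sum of the aligned
#' features; samples missing any feature value are excluded.
#'
#' @param feature_matrix samples x features numeric matrix.
#' @param feature_pair names (or indices) of the combined features.
#' @param orientation named +1/-1 vector per feature (+1 =
#'   non-responder-associated).
#' @return named per-sample score (NA for excluded samples).
#' @export
build_combinatorial_index <- function(feature_matrix, feature_pair,
                                      orientation) {
  fm <- as.matrix(feature_matrix)
  score <- rep(0, nrow(fm))
  for (f in feature_pair) {
    v <- fm[, f]
    mx <- max(abs(v), na.rm = TRUE)
    v_norm <- if (mx > 0) v / mx else v
    ori <- orientation[[f]] %||% 1
    score <- score + if (ori >= 0) v_norm else 1 - v_norm
  }
  stats::setNames(score, rownames(fm))
}

#' ROC AUC with a rank-sum test
#'
#' AUC by pairwise comparison with ties counted 1/2 (the Mann-Whitney
#' identity, computed from ranks); the accompanying p-value is the
#' two-sided Wilcoxon rank-sum test of the score difference between
#' classes. The orientation is flipped when needed so that the reported
#' AUC is >= 0.5.
#'
#' @param scores numeric scores.
#' @param binary_labels logical/0-1 labels (TRUE/1 = positive class).
#' @return list (auc, wilcoxon_p, orientation) where `orientation` is +1
#'   when higher scores indicate the positive class, else -1.
#' @export
roc_auc <- function(scores, binary_labels) {
  lab <- as.logical(binary_labels)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  keep <- !is.na(scores)
  scores <- scores[keep]; lab <- lab[keep]
  n1 <- sum(lab); n0 <- sum(!lab)
  r <- rank(scores)
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  orientation <- 1
  if (auc < 0.5) { auc <- 1 - auc; orientation <- -1 }
  p <- rank_sum_test(scores[lab], scores[!lab])
  list(auc = auc, wilcoxon_p = p, orientation = orientation)
}

#' Screen single features and feature pairs by ROC AUC
#'
#' Every candidate feature is screened alone; pairs are formed among the
#' `top_k` features ranked by univariate regression p-value, combined with
#' [build_combinatorial_index()]. All evaluated combinations get a
#' Wilcoxon p and a Benjamini-Hochberg q over the whole screen; results are
#' ranked by AUC (descending), then q.
#'
#' @param feature_matrix samples x features matrix.
#' @param response01 0/1 response (1 = non-responder).
#' @param candidate_features column names to screen (default all).
#' @param top_k pair pool size (default 6).
#' @return data.frame (name, type, auc, p, q, features) ranked.
#' @export
screen_combinations <- function(feature_matrix, response01,
                                candidate_features = colnames(feature_matrix),
                                top_k = 6) {
  fm <- as.matrix(feature_matrix[, candidate_features, drop = FALSE])
  uni <- lapply(candidate_features, function(f)
    univariate_regression(fm[, f], response01))
  names(uni) <- candidate_features
  usable <- candidate_features[vapply(uni, function(u) u$flag == "ok", logical(1))]
  orientation <- vapply(uni[usable], function(u) sign(u$coefficient), numeric(1))
  orientation[orientation == 0] <- 1
  rows <- list()
  add_row <- function(name, type, scores, features) {
    rr <- roc_auc(scores, response01 == 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, type = type, auc = rr$auc, p = rr$wilcoxon_p,
      features = features, stringsAsFactors = FALSE)
  }
  for (f in usable) add_row(f, "single", fm[, f], f)
  pool <- usable[order(vapply(uni[usable], `[[`, numeric(1), "p"))]
  pool <- utils::head(pool, top_k)
  if (length(pool) >= 2) {
    prs <- utils::combn(pool, 2, simplify = FALSE)
    for (pr in prs) {
      idx <- build_combinatorial_index(fm, pr, orientation)
      add_row(paste(pr, collapse = "+"), "pair", idx,
              paste(pr, collapse = "|"))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-out$auc, out$q, out$name), ]
  rownames(out) <- NULL
  out[, c("name", "type", "auc", "p", "q", "features")]
}
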