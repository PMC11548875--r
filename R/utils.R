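# Small internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Row variances of a dense matrix (two-pass, denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# One Dirichlet draw via normalized gamma variates.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha / sum(alpha) # degenerate guard for tiny alphas
  g / sum(g)
}

# Clip values symmetrically at +/- bound.
clip_abs <- function(x, bound) {
  x[x > bound] <- bound
  x[x < -bound] <- -bound
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
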