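# Internal numerical helpers shared across modules.

# -log10 p for a chi-square upper tail, computed in log space so that
# statistics far beyond double-precision tail underflow (p < 1e-300) keep a
# finite, exact -log10(p).
chisq_log10p <- function(statistic, df) {
  -pchisq(statistic, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# -log10 p for a two-sided normal test on a z-score, tail-safe.
normal_log10p <- function(z) {
  -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
}

# Back-transform where representable; 0 underflow is acceptable for display.
log10p_to_p <- function(log10p) 10^(-log10p)

# -log10 of the genome-wide threshold 5e-8, used for log-space comparisons.
log10_gw <- function(threshold = 5e-8) -log10(threshold)

check_square_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  invisible(m)
}

# Cholesky-like symmetric factor via eigendecomposition; fails naming the
# offending eigenvalue when the matrix is not positive definite.
symmetric_factor <- function(m, name = "matrix", tol = 1e-10) {
  check_square_symmetric(m, name)
  e <- eigen(m, symmetric = TRUE)
  bad <- which(e$values <= tol * max(abs(e$values)))
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` is not positive definite: eigenvalue %d is %.3e.",
      name, min(bad), e$values[min(bad)]
    ))
  }
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

# Deterministic child seeds so that one user-facing seed drives several
# independent random stages without reuse. Kept below 2^31.
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 2017L + as.integer(stage) * 7919L
}
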