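#' Residual z-score covariance under the null
#'
#' Container for the k x k cross-trait covariance of z-scores at null SNPs
#' (the critical input of the omnibus test), together with its provenance
#' and condition number. Off-diagonal structure arises from phenotypic
#' correlation combined with sample overlap between the per-trait GWAS.
#'
#' @param omega Symmetric k x k matrix with trait labels as dimnames.
#' @param provenance One of "formula", "ldsc-intercept", "direct".
#' @param se Optional matrix of entrywise standard errors.
#' @return An object of class `null_cov`.
#' @export
null_cov <- function(omega, provenance = c("direct", "formula", "ldsc-intercept"),
                     se = NULL) {
  provenance <- match.arg(provenance)
  check_square_symmetric(omega, "omega")
  if (is.null(colnames(omega))) {
    dimnames(omega) <- list(
      paste0("trait", seq_len(ncol(omega))), paste0("trait", seq_len(ncol(omega)))
    )
  }
  if (any(diag(omega) < 0.5 | diag(omega) > 2)) {
    warn("omega diagonal outside [0.5, 2]; check trait scaling.")
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(
      omega = omega, traits = colnames(omega), provenance = provenance,
      se = se, condition_number = max(abs(ev)) / max(min(abs(ev)), .Machine$double.eps)
    ),
    class = "null_cov"
  )
}

#' @export
print.null_cov <- function(x, ...) {
  cat(sprintf(
    "<null_cov> %d traits, provenance %s, condition number %.3g\n",
    length(x$traits), x$provenance, x$condition_number
  ))
  invisible(x)
}

#' @method tidy null_cov
#' @export
tidy.null_cov <- function(x, ...) {
  k <- length(x$traits)
  tibble(
    trait1 = rep(x$traits, times = k),
    trait2 = rep(x$traits, each = k),
    omega = as.vector(x$omega),
    se = if (is.null(x$se)) NA_real_ else as.vector(x$se)
  )
}

#' @method glance null_cov
#' @export
glance.null_cov <- function(x, ...) {
  tibble(
    n_traits = length(x$traits),
    provenance = x$provenance,
    condition_number = x$condition_number,
    max_offdiag = max(abs(x$omega[upper.tri(x$omega)]), 0)
  )
}

#' Sample-overlap model of two-trait GWAS cohorts
#'
#' @param rho k x k total phenotypic covariance (correlation when traits are
#'   standardized).
#' @param n_s k x k matrix (or scalar) of pairwise shared sample counts.
#' @param n Named per-trait sample sizes.
#' @return An object of class `overlap_model`.
#' @export
overlap_model <- function(rho, n_s, n) {
  check_square_symmetric(rho, "rho")
  k <- ncol(rho)
  if (length(n_s) == 1) n_s <- matrix(n_s, k, k)
  check_square_symmetric(n_s, "n_s")
  if (any(n <= 0)) abort("per-trait sample sizes must be positive.")
  lim <- outer(n, n, pmin)
  if (any(n_s < 0 | n_s > lim + 1e-9)) {
    abort("shared counts must satisfy 0 <= n_s(i,j) <= min(n_i, n_j).")
  }
  diag(n_s) <- n
  if (is.null(colnames(rho))) {
    dimnames(rho) <- list(names(n), names(n))
  }
  structure(list(rho = rho, n_s = n_s, n = n), class = "overlap_model")
}

#' Null covariance from phenotypic correlation and sample overlap
#'
#' Computes `Omega_ij = rho_ij * n_s(i,j) / sqrt(n_i * n_j)`: the expected
#' cross-trait covariance of null z-scores. With full overlap
#' (`n_s = n_i = n_j`) this is exactly the Pearson correlation matrix of the
#' phenotypes; with disjoint cohorts the off-diagonals vanish.
#'
#' @param model An [overlap_model()].
#' @return A [null_cov()] with provenance `"formula"`.
#' @export
omega_from_overlap <- function(model) {
  stopifnot(inherits(model, "overlap_model"))
  omega <- model$rho * model$n_s / sqrt(outer(model$n, model$n))
  null_cov(omega, provenance = "formula")
}

# Weighted simple regression of y on x from block-wise sufficient statistics;
# returns the intercept, its delete-one-block jackknife estimates, and slope.
wls_intercept_jackknife <- function(x, y, w, block_id) {
  sums <- function(v) as.vector(rowsum(v, block_id))
  S <- cbind(
    w1 = sums(w), wx = sums(w * x), wxx = sums(w * x * x),
    wy = sums(w * y), wxy = sums(w * x * y)
  )
  tot <- colSums(S)
  est <- function(s) {
    det <- s["w1"] * s["wxx"] - s["wx"]^2
    a <- (s["wxx"] * s["wy"] - s["wx"] * s["wxy"]) / det
    b <- (s["w1"] * s["wxy"] - s["wx"] * s["wy"]) / det
    c(intercept = unname(a), slope = unname(b))
  }
  full <- est(tot)
  jk <- apply(S, 1, function(row) est(tot - row)["intercept"])
  list(intercept = full[["intercept"]], slope = full[["slope"]], jackknife = jk)
}

#' Estimate the null covariance by LD-score regression intercepts
#'
#' For every trait pair (i, j), regresses the per-SNP product `z_i * z_j` on
#' the LD score with heteroskedasticity-motivated weights; the regression
#' intercept estimates `Omega_ij` free of polygenic contamination (which
#' loads on the slope), and the univariate regression of `z_i^2` supplies
#' the diagonal. Standard errors come from a delete-one block jackknife over
#' contiguous SNP blocks.
#'
#' @param panel A [z_panel()].
#' @param scores LD scores as returned by [ld_scores()] (matched by rsid).
#' @param n_blocks Number of contiguous jackknife blocks (default 200).
#' @param unit_diagonal Force the diagonal to exactly 1 instead of the
#'   univariate intercept (strict null-calibration semantics).
#' @param min_snps Minimum SNP count with scores required (default 2000).
#' @return A [null_cov()] with provenance `"ldsc-intercept"` and jackknife
#'   standard errors.
#' @export
estimate_omega_ldsc <- function(panel, scores, n_blocks = 200,
                                unit_diagonal = FALSE, min_snps = 2000) {
  stopifnot(inherits(panel, "z_panel"))
  ell <- scores$ld_score[match(panel$snps$rsid, scores$rsid)]
  ok <- !is.na(ell)
  if (sum(ok) < min_snps) {
    abort(sprintf("need >= %d SNPs with LD scores (got %d).", min_snps, sum(ok)))
  }
  if (stats::sd(ell[ok]) == 0) {
    abort("degenerate regression: LD scores are constant.")
  }
  z <- panel$z[ok, , drop = FALSE]
  ell <- ell[ok]
  traits <- colnames(z)
  k <- length(traits)
  omega <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  se <- omega

  # First pass: unweighted intercept/slope per pair, to build the variance
  # model used by the weights (expected z2 and expected product per SNP).
  fit_pair <- function(i, j, w) {
    y <- z[, i] * z[, j]
    keep <- !is.na(y)
    block_id <- ceiling(seq_len(sum(keep)) / ceiling(sum(keep) / n_blocks))
    wls_intercept_jackknife(ell[keep], y[keep], w[keep], block_id)
  }
  pass1 <- matrix(list(), k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      pass1[[i, j]] <- fit_pair(i, j, rep(1, nrow(z)))
    }
  }
  expected <- function(i, j) {
    f <- pass1[[min(i, j), max(i, j)]]
    pmax(f$intercept + f$slope * ell, if (i == j) 0.1 else -Inf)
  }
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- if (i == j) 2 * expected(i, i)^2 else {
        expected(i, i) * expected(j, j) + expected(i, j)^2
      }
      w <- 1 / (pmax(ell, 1) * pmax(v, 0.05))
      fit <- fit_pair(i, j, w)
      omega[i, j] <- omega[j, i] <- fit$intercept
      B <- length(fit$jackknife)
      se[i, j] <- se[j, i] <- sqrt((B - 1) / B * sum((fit$jackknife - mean(fit$jackknife))^2))
    }
  }
  if (unit_diagonal) diag(omega) <- 1
  null_cov(omega, provenance = "ldsc-intercept", se = se)
}

#' Condition-number diagnostic of a null covariance
#'
#' A nearly collinear trait set combined with high sample overlap yields an
#' ill-conditioned Omega, and the omnibus statistic then inflates wildly
#' (a null hypothesis that lacks robustness). This diagnostic reports the
#' ratio of extreme eigenvalues and flags matrices above the threshold;
#' downstream tests refuse flagged matrices unless they are regularized.
#'
#' @param cov A [null_cov()].
#' @param threshold Flagging threshold on the condition number (default 1e4).
#' @return A one-row tibble: condition_number, threshold, flagged,
#'   min_eigenvalue, max_eigenvalue.
#' @export
check_condition <- function(cov, threshold = 1e4) {
  stopifnot(inherits(cov, "null_cov"))
  ev <- eigen(cov$omega, symmetric = TRUE, only.values = TRUE)$values
  tibble(
    condition_number = cov$condition_number,
    threshold = threshold,
    flagged = cov$condition_number > threshold,
    min_eigenvalue = min(ev),
    max_eigenvalue = max(ev)
  )
}

#' Shrink a null covariance toward the identity
#'
#' `Omega' = (1 - lambda) Omega + lambda I`. An opt-in remedy for
#' ill-conditioned matrices; the provenance records the shrinkage so results
#' computed with a regularized Omega are identifiable.
#'
#' @param cov A [null_cov()].
#' @param lambda Shrinkage weight in `[0, 1]`.
#' @return A [null_cov()] with updated matrix and condition number.
#' @export
regularize <- function(cov, lambda) {
  stopifnot(inherits(cov, "null_cov"), lambda >= 0, lambda <= 1)
  omega <- (1 - lambda) * cov$omega + lambda * diag(ncol(cov$omega))
  dimnames(omega) <- dimnames(cov$omega)
  out <- null_cov(omega, provenance = cov$provenance, se = cov$se)
  attr(out, "lambda") <- lambda
  out
}

#' Write a null covariance as a TSV matrix with trait-label header
#' @param cov A [null_cov()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_null_cov <- function(cov, path) {
  utils::write.table(cov$omega, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a null covariance written by [write_null_cov()]
#' @param path TSV path.
#' @param provenance Provenance label to record.
#' @return A [null_cov()].
#' @export
read_null_cov <- function(path, provenance = "direct") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
  rownames(m) <- colnames(m)
  null_cov((m + t(m)) / 2, provenance = provenance)
}
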