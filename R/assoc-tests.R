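#' Omnibus multi-trait test at one SNP
#'
#' The joint chi-square test of a SNP's association across k traits:
#' `T = z' Omega^{-1} z`, which follows a chi-square distribution with k
#' degrees of freedom under the null of no genetic effect. Traits with a
#' missing z at this SNP are dropped and the degrees of freedom reduced
#' accordingly (filling zeros would deflate the statistic). The quadratic
#' form is computed through a linear solve, never an explicit inverse, and
#' p-values are carried as -log10 so extreme signals stay representable.
#'
#' @param z Named numeric vector of per-trait z-scores (`NA` = masked).
#' @param cov A [null_cov()] whose traits include the names of `z`.
#' @return A one-row tibble: statistic, df, p, log10p.
#' @export
omnibus_test <- function(z, cov) {
  stopifnot(inherits(cov, "null_cov"))
  # match traits by name when the names exist in the covariance, else by
  # position (a bare z vector against a bare omega)
  idx <- if (!is.null(names(z)) && all(names(z) %in% cov$traits)) {
    match(names(z), cov$traits)
  } else {
    seq_along(z)
  }
  keep <- idx[!is.na(z)]
  if (length(keep) == 0) abort("all traits masked at this SNP.")
  zz <- unname(z[!is.na(z)])
  omega <- cov$omega[keep, keep, drop = FALSE]
  stat <- tryCatch(
    sum(zz * solve(omega, zz)),
    error = function(e) abort(paste0(
      "singular null covariance; run check_condition() and consider regularize(): ",
      conditionMessage(e)
    ))
  )
  df <- length(zz)
  lp <- chisq_log10p(stat, df)
  tibble(statistic = stat, df = df, p = log10p_to_p(lp), log10p = lp)
}

# Vectorized omnibus over the rows of a z matrix sharing one missingness
# pattern (internal).
omnibus_rows <- function(zmat, omega) {
  sol <- solve(omega, t(zmat))
  colSums(t(zmat) * sol)
}

#' Genome-wide omnibus scan of a panel
#'
#' Applies the omnibus test at every SNP of a panel, adapting the degrees of
#' freedom to each SNP's missingness pattern, and reports alongside the
#' minimum univariate p-value across traits (uncorrected) used by the
#' novelty classification.
#'
#' @param panel A [z_panel()].
#' @param cov A [null_cov()] covering the panel traits.
#' @return A tibble: rsid, chrom, pos, statistic, df, log10p_joint,
#'   log10p_univ, univ_trait, imputed.
#' @export
omnibus_scan <- function(panel, cov) {
  stopifnot(inherits(panel, "z_panel"), inherits(cov, "null_cov"))
  z <- panel$z
  traits <- colnames(z)
  present <- !is.na(z)
  pattern <- apply(present, 1, function(r) paste(which(r), collapse = ","))
  stat <- rep(NA_real_, nrow(z)); df <- rep(NA_integer_, nrow(z))
  for (pat in unique(pattern)) {
    if (pat == "") next
    cols <- as.integer(strsplit(pat, ",")[[1]])
    rows <- which(pattern == pat)
    omega <- cov$omega[traits[cols], traits[cols], drop = FALSE]
    stat[rows] <- omnibus_rows(z[rows, cols, drop = FALSE], omega)
    df[rows] <- length(cols)
  }
  univ <- min_univariate_scan(panel)
  tibble(
    rsid = panel$snps$rsid, chrom = panel$snps$chrom, pos = panel$snps$pos,
    statistic = stat, df = df,
    log10p_joint = chisq_log10p(stat, df),
    log10p_univ = univ$log10p, univ_trait = univ$trait,
    imputed = if (is.null(panel$imputed)) FALSE else rowSums(panel$imputed) > 0
  ) |> filter(!is.na(.data$statistic))
}

#' Trans-ancestry omnibus test
#'
#' Cohorts of different ancestries are independent, so the per-ancestry
#' omnibus statistics add: `T_trans = sum_a z_a' Omega_a^{-1} z_a` follows a
#' chi-square with `sum_a k_a` degrees of freedom (trait counts may differ
#' across ancestries). No homogeneity of effects across ancestries is
#' assumed — each ancestry may deviate from the null in its own direction.
#'
#' @param parts List with one element per ancestry, each a list
#'   `list(z = named z vector, cov = null_cov)`.
#' @return A one-row tibble: statistic, df, p, log10p.
#' @export
trans_omnibus <- function(parts) {
  if (length(parts) == 0) abort("empty ancestry list.")
  pieces <- map(parts, function(p) omnibus_test(p$z, p$cov))
  stat <- sum(map_dbl(pieces, "statistic"))
  df <- sum(map_int(pieces, function(p) as.integer(p$df)))
  lp <- chisq_log10p(stat, df)
  tibble(statistic = stat, df = df, p = log10p_to_p(lp), log10p = lp)
}

#' Trans-ancestry omnibus scan over the SNP intersection
#'
#' Restricts to SNPs available in every ancestry (the trans analysis is
#' defined on the intersection), sums the per-ancestry omnibus statistics
#' per SNP and refers the sum to a chi-square with the summed degrees of
#' freedom.
#'
#' @param panels Named list of [z_panel()]s.
#' @param covs Named list of matching [null_cov()]s.
#' @return A tibble: rsid, chrom, pos, statistic, df, log10p_joint.
#' @export
trans_scan <- function(panels, covs) {
  stopifnot(length(panels) >= 1, identical(names(panels), names(covs)))
  shared <- Reduce(intersect, map(panels, function(p) p$snps$rsid))
  if (length(shared) == 0) abort("no SNP shared across all ancestries.")
  per <- imap(panels, function(p, a) {
    sub <- panel_subset(p, match(shared, p$snps$rsid))
    omnibus_scan(sub, covs[[a]]) |> select("rsid", "statistic", "df")
  })
  base <- panels[[1]]$snps |>
    filter(.data$rsid %in% shared) |>
    select("rsid", "chrom", "pos")
  acc <- per[[1]] |> rename(stat_total = "statistic", df_total = "df")
  if (length(per) > 1) {
    for (i in 2:length(per)) {
      acc <- acc |>
        inner_join(per[[i]], by = "rsid") |>
        mutate(
          stat_total = .data$stat_total + .data$statistic,
          df_total = .data$df_total + .data$df
        ) |>
        select("rsid", "stat_total", "df_total")
    }
  }
  base |>
    inner_join(acc, by = "rsid") |>
    mutate(
      statistic = .data$stat_total, df = .data$df_total,
      log10p_joint = chisq_log10p(.data$statistic, .data$df)
    ) |>
    select("rsid", "chrom", "pos", "statistic", "df", "log10p_joint")
}

#' Sample-size-weighted trans-ancestry meta-analysis z-score
#'
#' Fixed-effect combination `Z_meta = sum_a sqrt(N_a) z_a / sqrt(sum_a N_a)`
#' for one trait. Ancestries where the SNP is absent (`NA`) contribute
#' nothing and the weights renormalize over the present ancestries.
#'
#' @param z Per-ancestry z-scores (`NA` = SNP absent in that ancestry).
#' @param n Per-ancestry sample sizes.
#' @return The meta-analysis z-score.
#' @export
meta_z <- function(z, n) {
  stopifnot(length(z) == length(n))
  ok <- !is.na(z)
  if (!any(ok)) abort("SNP absent from every ancestry.")
  sum(sqrt(n[ok]) * z[ok]) / sqrt(sum(n[ok]))
}

#' Per-trait meta-analysis across a list of panels
#'
#' @param panels Named list of [z_panel()]s (ancestries).
#' @return A [z_panel()] on the union of SNPs whose z matrix holds the
#'   [meta_z()] combination per trait and whose `n` is the summed sample
#'   size.
#' @export
meta_panel <- function(panels) {
  stopifnot(length(panels) >= 1)
  traits <- Reduce(union, map(panels, panel_traits))
  snps <- bind_rows(map(panels, function(p) p$snps |> select("rsid", "chrom", "pos"))) |>
    distinct(.data$rsid, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  num <- matrix(0, nrow(snps), length(traits), dimnames = list(NULL, traits))
  den <- num
  for (p in panels) {
    i <- match(p$snps$rsid, snps$rsid)
    for (trait in panel_traits(p)) {
      zc <- p$z[, trait]
      ok <- !is.na(zc)
      num[i[ok], trait] <- num[i[ok], trait] + sqrt(p$n[[trait]]) * zc[ok]
      den[i[ok], trait] <- den[i[ok], trait] + p$n[[trait]]
    }
  }
  zmeta <- ifelse(den > 0, num / sqrt(pmax(den, 1)), NA_real_)
  n_tot <- map_dbl(traits, function(t) sum(map_dbl(panels, function(p) {
    if (t %in% panel_traits(p)) p$n[[t]] else 0
  })))
  z_panel(snps, zmeta, setNames(n_tot, traits))
}

#' Scale z-scores to a simulated smaller sample size
#'
#' `Z_sim = Z / sqrt(N_total) * sqrt(N_sim)`: the linear shrink of a z-score
#' under a hypothetical reduction of the GWAS sample, used to ask whether an
#' association would still be detected at a smaller cohort size. Downstream
#' p-values must be recomputed from the scaled z.
#'
#' @param z z-score(s).
#' @param n_total Actual sample size (> 0).
#' @param n_simulated Hypothetical sample size in `[0, n_total]`.
#' @return Scaled z-score(s).
#' @export
scale_z <- function(z, n_total, n_simulated) {
  if (any(n_total <= 0)) abort("n_total must be positive.")
  if (any(n_simulated < 0 | n_simulated > n_total)) {
    abort("n_simulated must lie in [0, n_total].")
  }
  z / sqrt(n_total) * sqrt(n_simulated)
}

#' Minimum univariate p-value across traits at one SNP
#'
#' Two-sided normal p-value per trait; the minimum is returned uncorrected
#' (deliberately: it makes the univariate reference as favorable as
#' possible, so "joint-only" discoveries are conservative).
#'
#' @param z Named per-trait z-scores (`NA` = masked).
#' @return A one-row tibble: p, log10p, trait.
#' @export
min_univariate_p <- function(z) {
  if (is.null(names(z))) names(z) <- paste0("trait", seq_along(z))
  ok <- !is.na(z)
  if (!any(ok)) abort("all traits masked at this SNP.")
  lp <- normal_log10p(z[ok])
  i <- which.max(lp)
  tibble(p = unname(log10p_to_p(lp[i])), log10p = unname(lp[i]),
         trait = names(lp)[i])
}

# Row-wise min univariate p over a panel (internal).
min_univariate_scan <- function(panel) {
  lp <- normal_log10p(panel$z)
  lp[is.na(panel$z)] <- -Inf
  best <- max.col(lp, ties.method = "first")
  has <- rowSums(!is.na(panel$z)) > 0
  tibble(
    log10p = ifelse(has, lp[cbind(seq_len(nrow(lp)), best)], NA_real_),
    trait = ifelse(has, colnames(panel$z)[best], NA_character_)
  )
}

#' Genomic inflation factor
#'
#' `lambda = median(statistic) / median of the reference chi-square`; values
#' near 1 indicate calibrated type-I error, values clearly above 1 indicate
#' residual confounding or a misspecified null covariance.
#'
#' @param statistics Chi-square statistics.
#' @param df Degrees of freedom of the reference distribution.
#' @return Scalar lambda.
#' @export
genomic_inflation <- function(statistics, df) {
  statistics <- statistics[!is.na(statistics)]
  if (length(statistics) < 1000) {
    warn("fewer than 1000 statistics; lambda estimate is noisy.")
  }
  median(statistics) / qchisq(0.5, df = df)
}
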