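#' Harmonized SNP-by-trait z-score panel
#'
#' The central container of the pipeline: a SNP index aligned to a reference
#' panel together with a SNP x trait matrix of association z-scores, the
#' per-trait GWAS sample sizes, and (optionally) flags marking imputed
#' entries. Missing trait-SNP combinations are `NA` in the z matrix; every
#' downstream test adapts its degrees of freedom to the per-SNP missingness
#' pattern rather than filling zeros.
#'
#' @param snps Data frame with one row per SNP; must contain `rsid`, `chrom`,
#'   `pos` and may carry panel alleles (`ref`, `alt`) and `maf`.
#' @param z Numeric matrix, `nrow(snps)` rows, one column per trait
#'   (column names are the trait labels). `NA` marks a missing entry.
#' @param n Named numeric vector of per-trait sample sizes, names matching
#'   `colnames(z)`.
#' @param imputed Optional logical matrix of the same shape as `z`, `TRUE`
#'   where the z-score was imputed rather than observed.
#' @param quality Optional numeric matrix of per-entry imputation quality
#'   (r-squared), `NA` for observed entries.
#' @param n_snp Optional numeric matrix of per-SNP, per-trait sample sizes
#'   (as read from the input files), used by [harmonize_sample_size()].
#'
#' @return An object of class `z_panel`.
#' @export
z_panel <- function(snps, z, n, imputed = NULL, quality = NULL, n_snp = NULL) {
  snps <- as_tibble(snps)
  stopifnot(is.matrix(z), nrow(z) == nrow(snps))
  if (!all(c("rsid", "chrom", "pos") %in% names(snps))) {
    abort("`snps` must contain columns rsid, chrom, pos.")
  }
  if (anyDuplicated(snps$rsid)) abort("duplicated rsid in panel index.")
  if (is.null(colnames(z))) abort("`z` must have trait names as colnames.")
  if (!setequal(names(n), colnames(z))) {
    abort("names of `n` must match the trait columns of `z`.")
  }
  n <- n[colnames(z)]
  if (any(is.nan(z) | is.infinite(z))) abort("non-finite z where mask says present.")
  if (!is.null(imputed)) stopifnot(identical(dim(imputed), dim(z)))
  if (!is.null(n_snp)) stopifnot(identical(dim(n_snp), dim(z)))
  structure(
    list(
      snps = snps, z = z, n = n, imputed = imputed, quality = quality,
      n_snp = n_snp
    ),
    class = "z_panel"
  )
}

#' @export
print.z_panel <- function(x, ...) {
  k <- ncol(x$z)
  miss <- mean(is.na(x$z))
  cat(sprintf(
    "<z_panel> %d SNPs x %d traits (%.1f%% missing)\n",
    nrow(x$z), k, 100 * miss
  ))
  cat("traits:", paste(colnames(x$z), collapse = ", "), "\n")
  if (!is.null(x$imputed)) {
    cat(sprintf("imputed entries: %d\n", sum(x$imputed, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
dim.z_panel <- function(x) dim(x$z)

#' Trait labels of a panel
#' @param panel A [z_panel].
#' @return Character vector of trait names.
#' @export
panel_traits <- function(panel) colnames(panel$z)

#' Tidy a z-score panel into long format
#'
#' @param x A [z_panel].
#' @param ... Unused.
#' @return A tibble with one row per present SNP-trait pair: rsid, chrom,
#'   pos, trait, z, n, imputed.
#' @method tidy z_panel
#' @export
tidy.z_panel <- function(x, ...) {
  long <- as_tibble(x$z) |>
    mutate(rsid = x$snps$rsid) |>
    pivot_longer(-"rsid", names_to = "trait", values_to = "z") |>
    filter(!is.na(.data$z))
  imp <- if (is.null(x$imputed)) {
    tibble(rsid = character(), trait = character(), imputed = logical())
  } else {
    as_tibble(x$imputed) |>
      mutate(rsid = x$snps$rsid) |>
      pivot_longer(-"rsid", names_to = "trait", values_to = "imputed")
  }
  long |>
    left_join(x$snps |> select("rsid", "chrom", "pos"), by = "rsid") |>
    left_join(imp, by = c("rsid", "trait")) |>
    mutate(
      imputed = if (is.null(x$imputed)) FALSE else .data$imputed %||% FALSE,
      n = unname(x$n[.data$trait])
    ) |>
    select("rsid", "chrom", "pos", "trait", "z", "n", "imputed")
}

#' One-row summary of a z-score panel
#' @param x A [z_panel].
#' @param ... Unused.
#' @return A one-row tibble: n_snps, n_traits, frac_missing, n_imputed.
#' @method glance z_panel
#' @export
glance.z_panel <- function(x, ...) {
  tibble(
    n_snps = nrow(x$z),
    n_traits = ncol(x$z),
    frac_missing = mean(is.na(x$z)),
    n_imputed = if (is.null(x$imputed)) 0L else sum(x$imputed, na.rm = TRUE)
  )
}

# Subset a panel to a SNP index vector (internal).
panel_subset <- function(panel, idx) {
  z_panel(
    snps = panel$snps[idx, , drop = FALSE],
    z = panel$z[idx, , drop = FALSE],
    n = panel$n,
    imputed = if (!is.null(panel$imputed)) panel$imputed[idx, , drop = FALSE],
    quality = if (!is.null(panel$quality)) panel$quality[idx, , drop = FALSE],
    n_snp = if (!is.null(panel$n_snp)) panel$n_snp[idx, , drop = FALSE]
  )
}
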