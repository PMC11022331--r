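#' Imputation accuracy-control parameters
#'
#' Defaults match the settings validated for real panels: a minimum
#' imputation quality of 0.6, at least 5 informative typed neighbors, and an
#' eigenvalue cutoff of 0.05 (relative to the largest eigenvalue) for the
#' pseudo-inverse of the typed-typed LD submatrix.
#'
#' @param r2_threshold Minimum predicted imputation r-squared below which an
#'   untyped SNP is left missing.
#' @param minimum_ld Minimum number of typed SNPs with `|r| > 0.2` to the
#'   target required to impute it.
#' @param eigen_threshold Relative eigenvalue cutoff of the pseudo-inverse.
#' @return An object of class `impute_params`.
#' @export
impute_params <- function(r2_threshold = 0.6, minimum_ld = 5,
                          eigen_threshold = 0.05) {
  if (r2_threshold < 0 || r2_threshold > 1) abort("r2_threshold must be in [0, 1].")
  if (minimum_ld < 0 || eigen_threshold < 0) abort("parameters must be nonnegative.")
  structure(
    list(
      r2_threshold = r2_threshold, minimum_ld = as.integer(minimum_ld),
      eigen_threshold = eigen_threshold
    ),
    class = "impute_params"
  )
}

# Eigenvalue-truncated pseudo-inverse: eigenvalues below cutoff * largest are
# discarded, guarding the conditional-expectation solve against the near-
# singular LD submatrices that arise among tightly linked typed SNPs.
truncated_pseudoinverse <- function(S, eigen_threshold) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values >= eigen_threshold * max(e$values)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

#' Impute untyped z-scores within one LD block
#'
#' Conditional-expectation imputation from summary statistics: for an
#' untyped SNP u, `z_hat_u = Sigma_ut %*% pinv(Sigma_tt) %*% z_t` with the
#' eigen-truncated pseudo-inverse, and predicted quality
#' `r2_u = Sigma_ut %*% pinv(Sigma_tt) %*% Sigma_tu` (clipped to [0, 1]).
#' SNPs with quality below `r2_threshold` or with fewer than `minimum_ld`
#' typed neighbors at `|r| > 0.2` are left missing. Typed SNPs pass through
#' unchanged.
#'
#' @param z_typed z-scores of the typed SNPs, in the order of `typed_index`.
#' @param ld Symmetric correlation matrix of the whole block.
#' @param typed_index Integer indices of the typed SNPs within the block.
#' @param params An [impute_params()].
#' @return A tibble with one row per block SNP: index, z, quality, imputed,
#'   n_neighbors. Filtered SNPs have `z = NA` and keep their computed
#'   quality.
#' @export
impute_block <- function(z_typed, ld, typed_index, params = impute_params()) {
  check_square_symmetric(ld, "ld")
  m <- nrow(ld)
  typed_index <- as.integer(typed_index)
  if (length(typed_index) == 0) abort("empty typed set: nothing to condition on.")
  stopifnot(length(z_typed) == length(typed_index), all(typed_index >= 1),
            all(typed_index <= m))
  untyped <- setdiff(seq_len(m), typed_index)

  out <- tibble(
    index = seq_len(m), z = NA_real_, quality = NA_real_,
    imputed = FALSE, n_neighbors = NA_integer_
  )
  out$z[typed_index] <- z_typed
  if (length(untyped) == 0) return(out)

  S_tt <- ld[typed_index, typed_index, drop = FALSE]
  P <- truncated_pseudoinverse(S_tt, params$eigen_threshold)
  S_ut <- ld[untyped, typed_index, drop = FALSE]
  z_hat <- as.vector(S_ut %*% (P %*% z_typed))
  r2 <- pmin(pmax(rowSums((S_ut %*% P) * S_ut), 0), 1)
  n_neighbors <- rowSums(abs(S_ut) > 0.2)

  pass <- r2 >= params$r2_threshold & n_neighbors >= params$minimum_ld
  out$quality[untyped] <- r2
  out$n_neighbors[untyped] <- as.integer(n_neighbors)
  out$z[untyped[pass]] <- z_hat[pass]
  out$imputed[untyped[pass]] <- TRUE
  out
}

#' Impute all missing entries of a panel
#'
#' Applies [impute_block()] per LD block and per trait; imputed entries are
#' flagged (column semantics `imputed = 1`) and their predicted quality kept
#' alongside the z-scores so discovery can report imputed versus typed
#' leads.
#'
#' @param panel A [z_panel()] whose SNP index matches `ld` row order (by
#'   rsid).
#' @param ld An `ld_blocks` object covering the panel SNPs.
#' @param params An [impute_params()].
#' @return A [z_panel()] with imputed z-scores, `imputed` flags and
#'   `quality`.
#' @export
impute_panel <- function(panel, ld, params = impute_params()) {
  stopifnot(inherits(panel, "z_panel"), inherits(ld, "ld_blocks"))
  row_of <- match(ld$snps$rsid, panel$snps$rsid)
  z <- panel$z
  imputed <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
  quality <- matrix(NA_real_, nrow(z), ncol(z), dimnames = dimnames(z))
  blocks <- ld_block_index(ld)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    rows <- row_of[idx]
    present_block <- !is.na(rows)
    if (!any(present_block)) next
    R <- ld$matrices[[b]][present_block, present_block, drop = FALSE]
    rows <- rows[present_block]
    for (trait in colnames(z)) {
      typed <- which(!is.na(z[rows, trait]))
      un <- which(is.na(z[rows, trait]))
      if (length(typed) == 0 || length(un) == 0) next
      res <- impute_block(z[rows[typed], trait], R, typed, params)
      filled <- res$imputed
      z[rows[filled], trait] <- res$z[filled]
      imputed[rows[filled], trait] <- TRUE
      quality[rows, trait][res$index[!is.na(res$quality)]] <-
        res$quality[!is.na(res$quality)]
    }
  }
  z_panel(panel$snps, z, panel$n, imputed = imputed, quality = quality,
          n_snp = panel$n_snp)
}

#' Hold-out assessment of imputation accuracy
#'
#' Randomly masks a fraction of the observed SNPs, imputes them back from
#' the remaining typed SNPs, and reports the per-trait Pearson correlation
#' between held-out and imputed z-scores together with the fraction of
#' masked SNPs that survived the quality filters.
#'
#' @param panel A [z_panel()].
#' @param ld Matching `ld_blocks`.
#' @param mask_fraction Fraction of observed SNPs to hold out, in (0, 1).
#' @param params An [impute_params()].
#' @param seed Integer seed for the mask draw.
#' @return A tibble: trait, correlation, n_masked, n_imputed, retention.
#'   Traits where nothing passed the filter report `correlation = NA`.
#' @export
mask_and_assess <- function(panel, ld, mask_fraction, params = impute_params(),
                            seed = 1L) {
  stopifnot(mask_fraction >= 0, mask_fraction < 1)
  set.seed(seed)
  n_mask <- round(mask_fraction * nrow(panel$z))
  if (n_mask == 0) {
    inform("mask fraction leaves no SNP held out; empty assessment.")
    return(tibble(
      trait = character(), correlation = double(), n_masked = integer(),
      n_imputed = integer(), retention = double()
    ))
  }
  held <- sort(sample.int(nrow(panel$z), n_mask))
  masked <- panel
  masked$z <- panel$z
  masked$z[held, ] <- NA_real_
  masked <- z_panel(panel$snps, masked$z, panel$n, n_snp = panel$n_snp)
  refilled <- impute_panel(masked, ld, params)
  map(colnames(panel$z), function(trait) {
    truth <- panel$z[held, trait]
    imp <- refilled$z[held, trait]
    got <- refilled$imputed[held, trait] & !is.na(truth)
    if (sum(got) < 3) {
      tibble(
        trait = trait, correlation = NA_real_, n_masked = length(held),
        n_imputed = sum(got), retention = mean(got)
      )
    } else {
      tibble(
        trait = trait, correlation = cor(truth[got], imp[got]),
        n_masked = length(held), n_imputed = sum(got), retention = mean(got)
      )
    }
  }) |> bind_rows()
}
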