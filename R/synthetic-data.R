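#' Specification of a block-structured LD layout
#'
#' Describes the linkage-disequilibrium structure simulated for one ancestry:
#' a chromosome partitioned into independent blocks, each with AR(1)
#' correlation `decay^|i-j|` between SNPs `i` and `j`. AR(1) blocks with
#' `decay < 1` are always positive definite, so the layout is a valid
#' correlation matrix by construction.
#'
#' @param n_snps Total number of SNPs.
#' @param block_sizes Integer vector of block sizes; must sum to `n_snps`.
#' @param decay Correlation between adjacent SNPs within a block, in
#'   `[0, 1)`; a vector (recycled over blocks) gives heterogeneous LD
#'   strength along the chromosome, which also spreads the LD scores — the
#'   spread LD-score regression needs for identification.
#' @param chrom Chromosome label for the simulated SNPs.
#' @param spacing_bp Base-pair spacing between adjacent simulated SNPs.
#' @return An object of class `ld_spec`.
#' @export
ld_spec <- function(n_snps, block_sizes, decay, chrom = "1", spacing_bp = 1000L) {
  if (sum(block_sizes) != n_snps) abort("block sizes must sum to n_snps.")
  if (any(block_sizes < 1)) abort("block sizes must be positive.")
  if (any(decay < 0 | decay >= 1)) {
    abort("`decay` must be in [0, 1): decay >= 1 gives a singular block.")
  }
  structure(
    list(
      n_snps = as.integer(n_snps), block_sizes = as.integer(block_sizes),
      decay = rep(decay, length.out = length(block_sizes)), chrom = chrom,
      spacing_bp = as.integer(spacing_bp)
    ),
    class = "ld_spec"
  )
}

#' Build block-diagonal LD correlation matrices
#'
#' Materializes the layout described by an [ld_spec()] as a list of dense
#' within-block correlation matrices plus a SNP index. Entry `(i, j)` of a
#' block is `decay^|i-j|`; SNPs in different blocks are uncorrelated.
#'
#' @param spec An [ld_spec()].
#' @return An object of class `ld_blocks`: `$snps` (tibble rsid, chrom, pos,
#'   block) and `$matrices` (list of symmetric unit-diagonal matrices).
#' @export
make_ld_blocks <- function(spec) {
  stopifnot(inherits(spec, "ld_spec"))
  mats <- map2(spec$block_sizes, spec$decay, function(m, d) {
    idx <- seq_len(m)
    d^abs(outer(idx, idx, "-"))
  })
  snps <- tibble(
    rsid = sprintf("rs%06d", seq_len(spec$n_snps)),
    chrom = spec$chrom,
    pos = seq_len(spec$n_snps) * spec$spacing_bp,
    block = rep(seq_along(spec$block_sizes), spec$block_sizes)
  )
  structure(list(snps = snps, matrices = mats), class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  cat(sprintf(
    "<ld_blocks> %d SNPs in %d blocks (sizes %s)\n",
    nrow(x$snps), length(x$matrices),
    paste(utils::head(map_int(x$matrices, nrow), 8), collapse = ", ")
  ))
  invisible(x)
}

# Dense block-diagonal correlation matrix (internal; small instances only).
ld_as_matrix <- function(ld) {
  n <- nrow(ld$snps)
  R <- diag(n)
  off <- 0L
  for (m in ld$matrices) {
    idx <- off + seq_len(nrow(m))
    R[idx, idx] <- m
    off <- off + nrow(m)
  }
  R
}

# Row index ranges of each block (internal).
ld_block_index <- function(ld) {
  sizes <- map_int(ld$matrices, nrow)
  ends <- cumsum(sizes)
  map2(ends - sizes + 1L, ends, seq)
}

#' Ground truth of a simulated multi-ancestry study
#'
#' Holds everything the generator needs to produce z-score panels with known
#' answers: standardized SNP effects, the cross-trait residual covariance
#' induced by sample overlap, per-trait sample sizes, and per-ancestry
#' availability masks emulating variants that are rare or absent (MAF < 1%)
#' in some ancestries.
#'
#' @param gamma SNP x trait matrix of standardized effects: `sqrt(N) * gamma`
#'   is the expected z-score, so effects live on the z scale and no
#'   allele-frequency bookkeeping is needed.
#' @param omega k x k residual z-score covariance under the null; must be
#'   symmetric positive definite with diagonal close to 1.
#' @param n Named per-trait sample sizes.
#' @param masks Optional named list (one element per ancestry) of logical
#'   vectors over SNPs, `TRUE` where the variant exists in that ancestry.
#' @return An object of class `study_truth`.
#' @export
study_truth <- function(gamma, omega, n, masks = NULL) {
  stopifnot(is.matrix(gamma), is.matrix(omega))
  check_square_symmetric(omega, "omega")
  if (any(abs(diag(omega) - 1) > 1)) abort("omega diagonal must be unit scale.")
  if (is.null(colnames(gamma))) colnames(gamma) <- names(n)
  if (!setequal(colnames(gamma), names(n))) {
    abort("gamma columns and names(n) must agree.")
  }
  if (ncol(omega) != ncol(gamma)) abort("omega dimension must match trait count.")
  dimnames(omega) <- list(colnames(gamma), colnames(gamma))
  structure(
    list(gamma = gamma, omega = omega, n = n[colnames(gamma)], masks = masks),
    class = "study_truth"
  )
}

#' Simulate a z-score panel for one ancestry
#'
#' Draws `Z = R Gamma diag(sqrt(N)) + L_R E L_Omega'`, where `R` is the
#' block-diagonal LD matrix, `Gamma` the standardized effects, and
#' `L_R, L_Omega` symmetric factors of the LD and residual covariances, so
#' that the noise has row covariance `R` and column covariance `Omega`
#' (`vec(noise) ~ N(0, Omega (x) R)`). Under `Gamma = 0`, each SNP's trait
#' vector is multivariate normal with covariance `Omega`.
#'
#' @param ld An [make_ld_blocks()] result.
#' @param truth A [study_truth()].
#' @param seed Integer seed; one seed yields a bit-identical panel.
#' @param ancestry Optional name of a mask in `truth$masks`; masked SNPs are
#'   dropped from the returned panel entirely.
#' @param traits Optional subset of trait labels to simulate (e.g. an
#'   ancestry whose study lacks some traits).
#' @return A [z_panel()].
#' @export
simulate_z_panel <- function(ld, truth, seed, ancestry = NULL, traits = NULL) {
  stopifnot(inherits(ld, "ld_blocks"), inherits(truth, "study_truth"))
  traits <- traits %||% colnames(truth$gamma)
  gamma <- truth$gamma[, traits, drop = FALSE]
  omega <- truth$omega[traits, traits, drop = FALSE]
  n <- truth$n[traits]
  p <- nrow(ld$snps)
  if (nrow(gamma) != p) abort("gamma rows must match the LD SNP count.")
  L_omega <- symmetric_factor(omega, "omega")

  set.seed(seed)
  E <- matrix(rnorm(p * length(traits)), p, length(traits))
  Z <- matrix(0, p, length(traits), dimnames = list(NULL, traits))
  scale_n <- sqrt(n)
  blocks <- ld_block_index(ld)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    R <- ld$matrices[[b]]
    L_R <- if (nrow(R) == 1) matrix(sqrt(R), 1, 1) else t(chol(R))
    mean_b <- R %*% gamma[idx, , drop = FALSE] %*% diag(scale_n, length(traits))
    Z[idx, ] <- mean_b + L_R %*% E[idx, , drop = FALSE] %*% t(L_omega)
  }

  snps <- ld$snps |> select("rsid", "chrom", "pos")
  if (!is.null(ancestry) && !is.null(truth$masks[[ancestry]])) {
    keep <- truth$masks[[ancestry]]
    blk <- ld$snps$block
    if (any(tapply(keep, blk, sum) < 1)) {
      abort("ancestry mask must leave at least one SNP per LD block.")
    }
    snps <- snps[keep, , drop = FALSE]
    Z <- Z[keep, , drop = FALSE]
  }
  z_panel(snps, Z, n)
}

#' Simulate a full multi-ancestry study
#'
#' Produces one harmonized z-score panel per ancestry from a shared truth
#' record, applying per-ancestry availability masks, trait subsets, and an
#' optional per-ancestry perturbation of the effect vectors (to emulate
#' ancestry-divergent multi-trait signals).
#'
#' @param ancestries Named list; each element is a list with components
#'   `ld` (an `ld_blocks` or `ld_spec`), optional `traits` (character subset),
#'   and optional `gamma_sd` (sd of N(0, gamma_sd) noise added to nonzero
#'   effects for this ancestry).
#' @param truth A [study_truth()]; `truth$masks` entries are matched to
#'   ancestry names.
#' @param seed Integer seed.
#' @return A list with `panels` (named list of [z_panel()]), `ld` (named list
#'   of `ld_blocks`), `truth`, and `gamma` (named list of the per-ancestry
#'   effect matrices actually used, sufficient to score discovery).
#' @export
simulate_study <- function(ancestries, truth, seed) {
  if (length(ancestries) < 1) abort("need at least one ancestry.")
  panels <- list(); lds <- list(); gammas <- list()
  for (i in seq_along(ancestries)) {
    name <- names(ancestries)[i]
    a <- ancestries[[i]]
    ld <- if (inherits(a$ld, "ld_spec")) make_ld_blocks(a$ld) else a$ld
    traits <- a$traits %||% colnames(truth$gamma)
    if (length(traits) == 0) abort("empty trait set for ancestry ", name)
    gamma_a <- truth$gamma
    if (!is.null(a$gamma_sd) && a$gamma_sd > 0) {
      set.seed(derive_seed(seed, 100L + i))
      nz <- gamma_a != 0
      gamma_a[nz] <- gamma_a[nz] + rnorm(sum(nz), sd = a$gamma_sd)
    }
    truth_a <- study_truth(gamma_a, truth$omega, truth$n, truth$masks)
    panels[[name]] <- simulate_z_panel(
      ld, truth_a, seed = derive_seed(seed, i),
      ancestry = name, traits = traits
    )
    lds[[name]] <- ld
    gammas[[name]] <- gamma_a
  }
  list(panels = panels, ld = lds, truth = truth, gamma = gammas)
}

#' Run a simulated study from a declarative config file
#'
#' Reads a YAML description of a synthetic study (keys: `traits`, `sample_size`,
#' `omega_offdiag`, `ancestries` with per-ancestry `n_snps`, `block_size`,
#' `decay`, optional `traits` and `mask_fraction`, plus `causal_fraction`,
#' `effect_size`, `seed`) and simulates it.
#'
#' @param path Path to the YAML config.
#' @param seed Optional override of the config's seed.
#' @return As [simulate_study()].
#' @export
simulate_study_from_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  seed <- seed %||% cfg$seed %||% 1L
  traits <- cfg$traits
  k <- length(traits)
  omega <- matrix(cfg$omega_offdiag %||% 0, k, k)
  diag(omega) <- 1
  n <- setNames(rep(cfg$sample_size, length.out = k), traits)
  n_snps <- cfg$ancestries[[1]]$n_snps
  set.seed(derive_seed(seed, 999L))
  gamma <- matrix(0, n_snps, k, dimnames = list(NULL, traits))
  n_causal <- round((cfg$causal_fraction %||% 0) * n_snps)
  if (n_causal > 0) {
    causal <- sample.int(n_snps, n_causal)
    gamma[causal, ] <- rnorm(n_causal * k, sd = cfg$effect_size %||% 0.01)
  }
  masks <- NULL
  ancestries <- map(cfg$ancestries, function(a) {
    sizes <- rep(a$block_size, ceiling(a$n_snps / a$block_size))
    sizes[length(sizes)] <- a$n_snps - sum(sizes[-length(sizes)])
    list(
      ld = ld_spec(a$n_snps, sizes, a$decay),
      traits = a$traits %||% traits
    )
  })
  names(ancestries) <- map(cfg$ancestries, "name")
  mask_list <- list()
  for (a in cfg$ancestries) {
    if (!is.null(a$mask_fraction) && a$mask_fraction > 0) {
      set.seed(derive_seed(seed, 500L + match(a$name, names(ancestries))))
      mask_list[[a$name]] <- stats::runif(n_snps) >= a$mask_fraction
    }
  }
  truth <- study_truth(gamma, omega, n, masks = if (length(mask_list)) mask_list)
  simulate_study(ancestries, truth, seed)
}

#' Write a panel as per-trait summary-statistics files
#'
#' Emits one tab-separated file per trait in the same dialect
#' [read_sumstats()] accepts (rsid, chrom, pos, effect_allele, other_allele,
#' z, n, maf), so simulated studies can exercise the full read/harmonize
#' path.
#'
#' @param panel A [z_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named by trait).
#' @export
write_sumstats <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snps <- panel$snps
  if (!"ref" %in% names(snps)) snps$ref <- "G"
  if (!"alt" %in% names(snps)) snps$alt <- "A"
  if (!"maf" %in% names(snps)) snps$maf <- 0.25
  paths <- setNames(
    file.path(dir, paste0(colnames(panel$z), ".tsv")),
    colnames(panel$z)
  )
  for (trait in colnames(panel$z)) {
    keep <- !is.na(panel$z[, trait])
    out <- tibble(
      rsid = snps$rsid[keep], chrom = snps$chrom[keep], pos = snps$pos[keep],
      effect_allele = snps$alt[keep], other_allele = snps$ref[keep],
      z = panel$z[keep, trait], n = panel$n[[trait]], maf = snps$maf[keep]
    )
    readr::write_tsv(out, paths[[trait]])
  }
  invisible(paths)
}
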