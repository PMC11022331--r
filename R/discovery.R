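#' Clumping parameters
#'
#' Defaults follow standard genome-wide practice: leads at p <= 5e-8, clump
#' members at p <= 5e-4 within r^2 >= 0.2 of the lead.
#'
#' @param p1 Lead significance threshold.
#' @param p2 Member significance threshold (p1 <= p2).
#' @param r2 LD threshold for clump membership, in (0, 1).
#' @return An object of class `clump_params`.
#' @export
clump_params <- function(p1 = 5e-8, p2 = 5e-4, r2 = 0.2) {
  if (p1 > p2) abort("p1 must be <= p2.")
  if (r2 <= 0 || r2 >= 1) abort("r2 must be in (0, 1).")
  structure(list(p1 = p1, p2 = p2, r2 = r2), class = "clump_params")
}

#' Scan LD-independent regions for candidate associations
#'
#' For each region, retrieves the minimum joint and minimum univariate
#' p-value over its SNPs; regions whose joint minimum clears the
#' genome-wide threshold are flagged for clumping. SNPs falling outside all
#' regions are reported and excluded.
#'
#' @param results Scan tibble from [omnibus_scan()] (needs chrom, pos,
#'   log10p_joint, log10p_univ); a `region` column is honored if present,
#'   otherwise assigned via [assign_regions()].
#' @param regions A `region_set`.
#' @param threshold Significance threshold on the joint p-value.
#' @return A tibble: region, n_snps, log10p_joint_min, log10p_univ_min,
#'   candidate.
#' @export
region_scan <- function(results, regions, threshold = 5e-8) {
  if (!"region" %in% names(results)) {
    results <- assign_regions(results, regions)
  }
  results |>
    filter(!is.na(.data$region)) |>
    group_by(.data$region) |>
    summarise(
      n_snps = n(),
      log10p_joint_min = max(.data$log10p_joint),
      log10p_univ_min = max(.data$log10p_univ, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(candidate = .data$log10p_joint_min >= -log10(threshold))
}

# Squared-correlation matrix between the given rsids, looked up from an LD
# block store (zero across blocks) or taken from a dense matrix (internal).
ld_r2_for <- function(ld, rsids) {
  if (is.matrix(ld)) {
    stopifnot(nrow(ld) == length(rsids))
    return(ld^2)
  }
  stopifnot(inherits(ld, "ld_blocks"))
  r2 <- matrix(0, length(rsids), length(rsids))
  loc <- match(rsids, ld$snps$rsid)
  if (anyNA(loc)) abort("some SNPs are missing from the LD store.")
  blk <- ld$snps$block[loc]
  blocks <- ld_block_index(ld)
  for (b in unique(blk)) {
    sel <- which(blk == b)
    within <- loc[sel] - min(blocks[[b]]) + 1L
    r2[sel, sel] <- ld$matrices[[b]][within, within, drop = FALSE]^2
  }
  diag(r2) <- 1
  r2
}

#' Greedy LD clumping of significant SNPs
#'
#' Repeatedly takes the smallest-p unassigned SNP with `p <= p1` as a lead
#' (ties broken by leftmost position) and assigns every unassigned SNP with
#' `p <= p2` and `r^2 >=` the threshold to its clump, until no eligible lead
#' remains. Each SNP joins at most one clump.
#'
#' @param results Tibble of SNPs in one region: rsid, pos, and the p column
#'   named by `p_col` (as -log10).
#' @param ld Dense correlation matrix aligned with `results` rows, or an
#'   `ld_blocks` store covering the rsids.
#' @param params A [clump_params()].
#' @param p_col Name of the -log10 p column to clump on.
#' @return A tibble with one row per clump member: clump, rsid, pos,
#'   log10p, is_lead, lead_rsid.
#' @export
clump <- function(results, ld, params = clump_params(), p_col = "log10p_joint") {
  lp <- results[[p_col]]
  if (is.null(lp)) abort(sprintf("column `%s` not found.", p_col))
  r2 <- ld_r2_for(ld, results$rsid)
  lp1 <- -log10(params$p1); lp2 <- -log10(params$p2)
  unassigned <- rep(TRUE, nrow(results))
  out <- list()
  clump_id <- 0L
  repeat {
    eligible <- which(unassigned & lp >= lp1)
    if (length(eligible) == 0) break
    lead <- eligible[order(-lp[eligible], results$pos[eligible])][1]
    members <- which(unassigned & lp >= lp2 & r2[lead, ] >= params$r2)
    members <- union(lead, members)
    unassigned[members] <- FALSE
    clump_id <- clump_id + 1L
    out[[clump_id]] <- tibble(
      clump = clump_id,
      rsid = results$rsid[members],
      pos = results$pos[members],
      log10p = lp[members],
      is_lead = members == lead,
      lead_rsid = results$rsid[lead]
    )
  }
  if (length(out) == 0) {
    return(tibble(
      clump = integer(), rsid = character(), pos = integer(),
      log10p = double(), is_lead = logical(), lead_rsid = character()
    ))
  }
  bind_rows(out)
}

#' Remove isolated leads
#'
#' Clumps containing only their lead SNP are discarded: a genome-wide
#' signal carried by a single SNP with no supporting neighbor is treated as
#' a poor-quality association.
#'
#' @param clumps Output of [clump()].
#' @return The filtered clump tibble; the number removed is reported.
#' @export
filter_isolated <- function(clumps) {
  sizes <- clumps |> count(.data$clump, name = "size")
  keep <- sizes$clump[sizes$size >= 2]
  dropped <- nrow(sizes) - length(keep)
  if (dropped > 0) inform(sprintf("removed %d isolated lead(s).", dropped))
  clumps |> filter(.data$clump %in% keep)
}

#' Flag associations found only by the joint test
#'
#' A lead SNP is a new association when its omnibus p-value is genome-wide
#' significant while its minimum univariate p-value across traits is not.
#' The univariate minimum is deliberately left uncorrected for multiple
#' traits, which makes the "new" label conservative. All comparisons are
#' done in -log10 space.
#'
#' @param associations Tibble with log10p_joint and log10p_univ columns.
#' @param threshold Genome-wide significance threshold (default 5e-8).
#' @return `associations` with a logical `new` column.
#' @export
classify_new <- function(associations, threshold = 5e-8) {
  gw <- -log10(threshold)
  associations |>
    mutate(new = .data$log10p_joint >= gw & .data$log10p_univ < gw)
}

#' Bonferroni-corrected novelty
#'
#' Recomputes significance and novelty at `threshold / n_analyses`, the
#' stricter criterion accounting for the number of multi-trait GWAS
#' performed; associations no longer significant for the joint test drop
#' out.
#'
#' @param associations Tibble with log10p_joint and log10p_univ columns.
#' @param n_analyses Number of analyses corrected for (>= 1).
#' @param threshold Uncorrected threshold (default 5e-8).
#' @return The filtered, reclassified association tibble.
#' @export
bonferroni_variant <- function(associations, n_analyses, threshold = 5e-8) {
  if (n_analyses < 1) abort("n_analyses must be >= 1.")
  t_corr <- threshold / n_analyses
  associations |>
    filter(.data$log10p_joint >= -log10(t_corr)) |>
    classify_new(threshold = t_corr)
}

#' Lead selection for trans-ancestry results
#'
#' LD-independent regions cannot be defined across ancestries, so the
#' genome is partitioned into fixed-origin 1 Mbp bins
#' (`bin = floor((pos - 1) / 1e6)`) and the minimum-p SNP per bin is
#' returned when it clears the significance threshold.
#'
#' @param results Tibble with chrom, pos and the -log10 p column named by
#'   `p_col`.
#' @param threshold Significance threshold (default 5e-8).
#' @param bin_bp Bin width in base pairs (default 1e6).
#' @param p_col -log10 p column to rank on.
#' @return One row per significant bin: chrom, bin, plus the lead SNP's
#'   columns.
#' @export
trans_lead_selection <- function(results, threshold = 5e-8, bin_bp = 1e6,
                                 p_col = "log10p_joint") {
  results |>
    mutate(bin = floor((.data$pos - 1) / bin_bp)) |>
    filter(.data[[p_col]] >= -log10(threshold)) |>
    group_by(.data$chrom, .data$bin) |>
    arrange(desc(.data[[p_col]]), .data$pos, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
}

#' End-to-end discovery for one ancestry
#'
#' Runs the two-step procedure: scan LD-independent regions for a
#' genome-wide significant joint minimum, clump each candidate region on
#' the joint p-value, drop isolated leads, and classify novelty of the
#' surviving leads.
#'
#' @param results Scan tibble from [omnibus_scan()].
#' @param regions A `region_set`.
#' @param ld LD store (`ld_blocks`) for r^2 lookups.
#' @param params A [clump_params()].
#' @param ancestry Ancestry label carried into the output.
#' @return Association tibble: ancestry, region, rsid, chrom, pos,
#'   log10p_joint, log10p_univ, n_members, imputed, new.
#' @export
discover <- function(results, regions, ld, params = clump_params(),
                     ancestry = NA_character_) {
  results <- if ("region" %in% names(results)) results else
    assign_regions(results, regions)
  cands <- region_scan(results, regions, threshold = params$p1) |>
    filter(.data$candidate)
  leads <- map(cands$region, function(r) {
    in_region <- results |> filter(.data$region == r)
    cl <- clump(in_region, ld, params) |> filter_isolated()
    if (nrow(cl) == 0) return(NULL)
    cl |>
      group_by(.data$clump) |>
      summarise(
        rsid = .data$rsid[.data$is_lead],
        n_members = n(), .groups = "drop"
      ) |>
      mutate(region = r)
  }) |> bind_rows()
  if (is.null(leads) || nrow(leads) == 0) {
    return(tibble(
      ancestry = character(), region = integer(), rsid = character(),
      chrom = character(), pos = integer(), log10p_joint = double(),
      log10p_univ = double(), n_members = integer(), imputed = logical(),
      new = logical()
    ))
  }
  leads |>
    left_join(results, by = c("rsid", "region")) |>
    mutate(ancestry = ancestry) |>
    select(
      "ancestry", "region", "rsid", "chrom", "pos",
      "log10p_joint", "log10p_univ", "n_members", "imputed"
    ) |>
    classify_new(threshold = params$p1)
}
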