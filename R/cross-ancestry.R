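# Distinct fixed-origin 1 Mbp bins occupied by a set of associations.
locus_bins <- function(df, bin_bp = 1e6) {
  df |>
    mutate(bin = floor((.data$pos - 1) / bin_bp)) |>
    distinct(.data$chrom, .data$bin)
}

#' Cross-ancestry locus overlap table
#'
#' Segments the genome into non-overlapping fixed 1 Mbp bins; a bin is
#' "detected" in an ancestry if it contains at least one significant
#' association (joint or univariate). The result gives UpSet-style
#' exclusive intersection counts over ancestries, each flagged when at
#' least one contributing association was found by the joint test alone.
#'
#' @param associations Tibble with ancestry, chrom, pos and logical `new`
#'   columns (one row per significant association, all ancestries stacked).
#' @param bin_bp Bin width in base pairs (default 1e6).
#' @return An `overlap_table` tibble: subset (ancestries joined by "+"),
#'   count, has_new; bin-level memberships are in the `"bins"` attribute.
#' @export
bin_loci <- function(associations, bin_bp = 1e6) {
  stopifnot(all(c("ancestry", "chrom", "pos") %in% names(associations)))
  if (!"new" %in% names(associations)) associations$new <- FALSE
  if (nrow(associations) == 0) {
    empty <- tibble(subset = character(), count = integer(), has_new = logical())
    return(structure(empty, class = c("overlap_table", class(empty)),
                     bins = tibble(chrom = character(), bin = double(),
                                   members = character(), has_new = logical())))
  }
  bins <- associations |>
    mutate(bin = floor((.data$pos - 1) / bin_bp)) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(
      members = paste(sort(unique(.data$ancestry)), collapse = "+"),
      has_new = any(.data$new),
      .groups = "drop"
    )
  table <- bins |>
    group_by(subset = .data$members) |>
    summarise(count = n(), has_new = any(.data$has_new), .groups = "drop") |>
    arrange(desc(.data$count))
  structure(table, class = c("overlap_table", class(table)), bins = bins)
}

#' Multi-trait signal similarity between two ancestries
#'
#' For every 1 Mbp bin where both ancestries have a lead association, pairs
#' one SNP per ancestry (the same variant when it leads in both, otherwise
#' each ancestry's own lead) and reports the squared Pearson correlation of
#' their multi-trait z-score vectors over the traits present in both
#' panels. Correlation on z-scores is equivalent to correlation on
#' standardized effects because the sample-size scaling is a constant per
#' ancestry.
#'
#' @param panel_a,panel_b [z_panel()]s of the two ancestries.
#' @param leads_a,leads_b Association tibbles (rsid, chrom, pos) of each
#'   ancestry's lead SNPs.
#' @param mode `"lead-pair"` (default) pairs each ancestry's own lead;
#'   `"same-snp"` only keeps bins where one variant leads in both.
#' @param bin_bp Bin width (default 1e6).
#' @return A tibble: chrom, bin, rsid_a, rsid_b, same_snp, n_traits, r2.
#' @export
signal_similarity <- function(panel_a, panel_b, leads_a, leads_b,
                              mode = c("lead-pair", "same-snp"), bin_bp = 1e6) {
  mode <- match.arg(mode)
  shared_traits <- intersect(panel_traits(panel_a), panel_traits(panel_b))
  if (length(shared_traits) < 3) {
    abort("need at least 3 shared traits for a meaningful correlation.")
  }
  with_bin <- function(df) df |> mutate(bin = floor((.data$pos - 1) / bin_bp))
  la <- with_bin(leads_a); lb <- with_bin(leads_b)
  pairs <- inner_join(
    la |> select("chrom", "bin", rsid_a = "rsid"),
    lb |> select("chrom", "bin", rsid_b = "rsid"),
    by = c("chrom", "bin"), relationship = "many-to-many"
  ) |>
    group_by(.data$chrom, .data$bin) |>
    mutate(same_snp = .data$rsid_a == .data$rsid_b) |>
    arrange(desc(.data$same_snp), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  if (mode == "same-snp") pairs <- pairs |> filter(.data$same_snp)

  pmap(pairs, function(chrom, bin, rsid_a, rsid_b, same_snp) {
    za <- panel_a$z[match(rsid_a, panel_a$snps$rsid), shared_traits]
    zb <- panel_b$z[match(rsid_b, panel_b$snps$rsid), shared_traits]
    ok <- !is.na(za) & !is.na(zb)
    if (sum(ok) < 3) return(NULL)
    tibble(
      chrom = chrom, bin = bin, rsid_a = rsid_a, rsid_b = rsid_b,
      same_snp = same_snp, n_traits = sum(ok),
      r2 = cor(za[ok], zb[ok])^2
    )
  }) |> bind_rows()
}

#' European-specificity under simulated downsampling
#'
#' Artificially weakens the z-scores of one ancestry's lead SNPs to emulate
#' a smaller cohort ([scale_z()] at each sample-size fraction), recomputes
#' joint and univariate p-values, and reports the fraction of 1 Mbp loci
#' that remain both detected and specific to that ancestry (not occupied by
#' the comparison ancestry). At fraction 1 this is the observed
#' specificity; at fraction 0 no association survives and the specificity
#' is 0.
#'
#' @param leads Lead tibble (rsid, chrom, pos) of the downsampled ancestry.
#' @param panel Its [z_panel()] (supplies the multi-trait z at each lead).
#' @param cov Its [null_cov()].
#' @param other_associations Associations of the comparison ancestry
#'   (chrom, pos), defining the occupied bins.
#' @param fractions Sample-size fractions to sweep (default 0..1 by 0.01).
#' @param threshold Significance threshold (default 5e-8).
#' @param bin_bp Bin width (default 1e6).
#' @return A tibble: fraction, n_detected, n_exclusive, specificity.
#'   Non-monotone dips of n_detected along the sweep are reported.
#' @export
downsample_specificity <- function(leads, panel, cov, other_associations,
                                   fractions = seq(0, 1, by = 0.01),
                                   threshold = 5e-8, bin_bp = 1e6) {
  gw <- -log10(threshold)
  rows <- match(leads$rsid, panel$snps$rsid)
  if (anyNA(rows)) abort("some lead SNPs are absent from the panel.")
  Z <- panel$z[rows, , drop = FALSE]
  other_bins <- locus_bins(other_associations, bin_bp) |>
    mutate(occupied = TRUE)
  lead_bins <- leads |> mutate(bin = floor((.data$pos - 1) / bin_bp))

  curve <- map(fractions, function(f) {
    Zf <- Z * sqrt(f)
    detected <- map_lgl(seq_len(nrow(Zf)), function(i) {
      z <- Zf[i, ]
      if (all(is.na(z))) return(FALSE)
      joint <- omnibus_test(z, cov)$log10p
      univ <- min_univariate_p(z)$log10p
      joint >= gw || univ >= gw
    })
    det_bins <- lead_bins[detected, , drop = FALSE] |>
      distinct(.data$chrom, .data$bin) |>
      left_join(other_bins, by = c("chrom", "bin"))
    n_det <- nrow(det_bins)
    n_exc <- sum(is.na(det_bins$occupied))
    tibble(
      fraction = f, n_detected = n_det, n_exclusive = n_exc,
      specificity = if (n_det > 0) n_exc / n_det else 0
    )
  }) |> bind_rows()
  dips <- diff(curve$n_detected) < 0
  if (any(dips)) {
    inform(sprintf(
      "detected-count curve dips at %d of %d steps (expected: shrinking z only removes signal).",
      sum(dips), length(dips)
    ))
  }
  curve
}
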