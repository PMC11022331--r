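#' Column dialect for summary-statistics files
#'
#' Maps the canonical field names of this package onto the column names used
#' by a particular file format. The default accepts GWAS-SSF-like headers.
#'
#' @param rsid,chrom,pos,effect_allele,other_allele,z,beta,se,n,maf Column
#'   names in the file for each canonical field; set `z` (or `beta`/`se`) to
#'   `NA` when the file lacks it.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_sumstats()].
#' @export
sumstats_dialect <- function(rsid = "rsid", chrom = "chrom", pos = "pos",
                             effect_allele = "effect_allele",
                             other_allele = "other_allele",
                             z = "z", beta = "beta", se = "se",
                             n = "n", maf = "maf") {
  c(
    rsid = rsid, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    z = z, beta = beta, se = se, n = n, maf = maf
  )
}

#' Read one trait's GWAS summary statistics
#'
#' Reads a delimited summary-statistics table, renames columns according to a
#' dialect map, computes `z = beta / se` where no z column is present, and
#' drops malformed rows (non-positive standard errors, identical or
#' non-ACGT alleles, missing values in mandatory fields), counting them in
#' the `n_malformed` attribute. When both z and beta/se are present the z
#' column wins; rows where the two disagree by more than 1e-6 are counted in
#' `n_discrepant`.
#'
#' @param path Path to a tab- (or `delim`-) separated file with a header.
#' @param dialect A [sumstats_dialect()] naming the columns.
#' @param delim Field delimiter.
#' @return A tibble with columns rsid, chrom, pos, effect_allele,
#'   other_allele, z, n, maf (NA when absent), plus attributes `n_malformed`
#'   and `n_discrepant`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), delim = "\t") {
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE
  )
  get_col <- function(field) {
    nm <- dialect[[field]]
    if (!is.na(nm) && nm %in% names(raw)) raw[[nm]] else NULL
  }
  mandatory <- c("rsid", "chrom", "pos", "effect_allele", "other_allele", "n")
  missing_cols <- mandatory[map_lgl(mandatory, function(f) is.null(get_col(f)))]
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory columns: ", paste(missing_cols, collapse = ", ")))
  }
  z <- get_col("z"); beta <- get_col("beta"); se <- get_col("se")
  if (is.null(z) && (is.null(beta) || is.null(se))) {
    abort("need either a z column or both beta and se columns.")
  }

  out <- tibble(
    rsid = as.character(get_col("rsid")),
    chrom = as.character(get_col("chrom")),
    pos = as.integer(get_col("pos")),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    n = as.numeric(get_col("n")),
    maf = if (is.null(get_col("maf"))) NA_real_ else as.numeric(get_col("maf"))
  )

  bad_se <- if (!is.null(se)) !is.na(se) & se <= 0 else rep(FALSE, nrow(out))
  n_discrepant <- 0L
  if (!is.null(z)) {
    out$z <- as.numeric(z)
    if (!is.null(beta) && !is.null(se)) {
      ratio <- beta / se
      n_discrepant <- sum(abs(out$z - ratio) > 1e-6 & !bad_se, na.rm = TRUE)
      if (n_discrepant > 0) {
        inform(sprintf(
          "%d rows where z and beta/se disagree by > 1e-6; z column kept.",
          n_discrepant
        ))
      }
    }
  } else {
    out$z <- ifelse(bad_se, NA_real_, as.numeric(beta) / as.numeric(se))
  }

  nucleotide <- function(a) grepl("^[ACGT]+$", a)
  malformed <- bad_se |
    is.na(out$rsid) | is.na(out$pos) | is.na(out$z) | is.na(out$n) |
    !nucleotide(out$effect_allele) | !nucleotide(out$other_allele) |
    out$effect_allele == out$other_allele
  if (any(malformed)) {
    inform(sprintf("dropped %d malformed rows from %s", sum(malformed), path))
  }
  out <- out[!malformed, , drop = FALSE]
  attr(out, "n_malformed") <- sum(malformed)
  attr(out, "n_discrepant") <- n_discrepant
  out
}

strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize per-trait summary statistics against a reference panel
#'
#' Restricts each trait's records to the reference panel of common variants
#' (panel MAF > `maf_min`), aligns alleles to the panel orientation (a
#' swapped effect/other allele pair flips the sign of z), drops
#' strand-ambiguous (A/T, C/G) and allele-mismatched records, resolves
#' duplicated rsids by keeping the record with the largest sample size, and
#' assembles the per-trait z columns on the union of surviving SNPs with a
#' missingness mask.
#'
#' @param records Named list of per-trait tibbles as returned by
#'   [read_sumstats()] (names are trait labels).
#' @param panel Reference-panel tibble with columns rsid, chrom, pos, ref,
#'   alt, maf.
#' @param maf_min Panel minor-allele-frequency floor; variants at or below it
#'   are excluded (default 0.01, i.e. MAF > 1%).
#' @return A [z_panel()] whose SNP index carries the panel coordinates and
#'   alleles, with per-SNP sample sizes retained for
#'   [harmonize_sample_size()].
#' @export
harmonize <- function(records, panel, maf_min = 0.01) {
  stopifnot(is.list(records), length(records) >= 1, !is.null(names(records)))
  panel <- as_tibble(panel) |>
    filter(.data$maf > maf_min) |>
    distinct(.data$rsid, .keep_all = TRUE)

  aligned <- imap(records, function(rec, trait) {
    rec <- as_tibble(rec) |>
      group_by(.data$rsid) |>
      dplyr::slice_max(order_by = .data$n, n = 1, with_ties = FALSE) |>
      ungroup() |>
      filter(!strand_ambiguous(.data$effect_allele, .data$other_allele)) |>
      inner_join(
        panel |> select("rsid", panel_ref = "ref", panel_alt = "alt"),
        by = "rsid"
      )
    same <- rec$effect_allele == rec$panel_alt & rec$other_allele == rec$panel_ref
    swap <- rec$effect_allele == rec$panel_ref & rec$other_allele == rec$panel_alt
    rec$z <- ifelse(swap, -rec$z, rec$z)
    rec[same | swap, c("rsid", "z", "n")]
  })

  snps <- panel |>
    filter(.data$rsid %in% unique(unlist(map(aligned, "rsid")))) |>
    arrange(.data$chrom, .data$pos) |>
    select("rsid", "chrom", "pos", "ref", "alt", "maf")
  if (nrow(snps) == 0) abort("no summary-statistics SNP matches the reference panel.")

  traits <- names(records)
  z <- matrix(NA_real_, nrow(snps), length(traits), dimnames = list(NULL, traits))
  n_snp <- z
  for (trait in traits) {
    i <- match(aligned[[trait]]$rsid, snps$rsid)
    z[i, trait] <- aligned[[trait]]$z
    n_snp[i, trait] <- aligned[[trait]]$n
  }
  n <- map_dbl(traits, function(t) median(n_snp[, t], na.rm = TRUE))
  z_panel(snps, z, setNames(n, traits), n_snp = n_snp)
}

#' Mask SNPs with atypically small per-SNP sample sizes
#'
#' Within each trait, computes the 90th percentile of the per-SNP sample
#' sizes and masks SNPs whose n falls below `min_fraction` of it; the
#' trait's scalar sample size is then set to the median n of the retained
#' SNPs. This removes variants measured in only a small sub-cohort, whose
#' z-scores are not exchangeable with the rest of the study.
#'
#' @param panel A [z_panel()] carrying per-SNP sample sizes.
#' @param min_fraction Fraction of the 90th-percentile n below which a SNP is
#'   masked for that trait (default 0.7; 0 disables the filter).
#' @return The filtered [z_panel()].
#' @export
harmonize_sample_size <- function(panel, min_fraction = 0.7) {
  stopifnot(inherits(panel, "z_panel"))
  if (is.null(panel$n_snp)) abort("panel lacks per-SNP sample sizes.")
  z <- panel$z
  n_snp <- panel$n_snp
  n <- panel$n
  for (trait in colnames(z)) {
    present <- !is.na(z[, trait])
    if (!any(present)) next
    q90 <- stats::quantile(n_snp[present, trait], 0.9, na.rm = TRUE)
    drop <- present & n_snp[, trait] < min_fraction * q90
    z[drop, trait] <- NA_real_
    n_snp[drop, trait] <- NA_real_
    kept <- !is.na(z[, trait])
    if (!any(kept)) {
      abort(sprintf("all SNPs masked for trait %s by the sample-size filter.", trait))
    }
    n[[trait]] <- median(n_snp[kept, trait], na.rm = TRUE)
  }
  z_panel(panel$snps, z, n, imputed = panel$imputed, n_snp = n_snp)
}

#' Read a reference-panel index
#'
#' @param path TSV with columns rsid, chrom, pos, ref, alt, maf.
#' @return A tibble.
#' @export
read_ref_panel <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(chrom = as.character(.data$chrom))
}
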