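test_that("locus binning produces exact exclusive intersections", {
  assoc <- tibble::tibble(
    ancestry = c("EUR", "EUR", "EAS", "EAS", "AFR"),
    chrom = c("1", "1", "1", "2", "1"),
    pos = c(500000L, 1500000L, 600000L, 500000L, 550000L),
    new = c(TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  ot <- bin_loci(assoc)
  tab <- tibble::as_tibble(ot)
  # chr1 bin0: EUR+EAS+AFR (with a joint-only EUR hit); chr1 bin1: EUR only;
  # chr2 bin0: EAS only
  expect_equal(sum(tab$count), 3)
  expect_equal(tab$count[tab$subset == "AFR+EAS+EUR"], 1)
  expect_true(tab$has_new[tab$subset == "AFR+EAS+EUR"])
  expect_equal(tab$count[tab$subset == "EUR"], 1)
  expect_false(tab$has_new[tab$subset == "EUR"])

  # single ancestry degenerates to its own bin count
  solo <- bin_loci(assoc[assoc$ancestry == "EUR", ])
  expect_equal(sum(tibble::as_tibble(solo)$count), 2)

  # identical association sets: everything falls in the pairwise intersection
  dup <- dplyr::bind_rows(
    assoc[assoc$ancestry == "EUR", ],
    assoc[assoc$ancestry == "EUR", ] |> dplyr::mutate(ancestry = "EAS")
  )
  both <- tibble::as_tibble(bin_loci(dup))
  expect_equal(both$subset, "EAS+EUR")
  expect_equal(both$count, 2)
})

test_that("intersection counts are invariant to ancestry order", {
  set.seed(8)
  assoc <- tibble::tibble(
    ancestry = sample(c("A", "B", "C"), 60, TRUE),
    chrom = sample(c("1", "2"), 60, TRUE),
    pos = sample.int(8e6, 60),
    new = sample(c(TRUE, FALSE), 60, TRUE)
  )
  t1 <- tibble::as_tibble(bin_loci(assoc)) |> dplyr::arrange(subset)
  t2 <- tibble::as_tibble(bin_loci(assoc[sample(60), ])) |> dplyr::arrange(subset)
  expect_equal(t1, t2)
})

make_pair_panels <- function(n_loci, k, noise_sd, seed, flip = FALSE,
                             perturb_sd = 0) {
  # two ancestries sharing lead SNPs at n_loci distinct 1 Mbp bins, with a
  # common multi-trait effect vector plus per-ancestry noise
  set.seed(seed)
  traits <- paste0("t", seq_len(k))
  mu <- matrix(rnorm(n_loci * k, sd = 4), n_loci, k)
  za <- mu + matrix(rnorm(n_loci * k, sd = noise_sd), n_loci, k)
  mu_b <- mu + matrix(rnorm(n_loci * k, sd = perturb_sd), n_loci, k)
  zb <- (if (flip) -1 else 1) * (mu_b + matrix(rnorm(n_loci * k, sd = noise_sd), n_loci, k))
  colnames(za) <- colnames(zb) <- traits
  snps <- tibble::tibble(
    rsid = paste0("lead", seq_len(n_loci)), chrom = "1",
    pos = as.integer(seq_len(n_loci) * 1e6 + 1) # one bin each
  )
  n <- stats::setNames(rep(1e4, k), traits)
  list(
    panel_a = z_panel(snps, za, n), panel_b = z_panel(snps, zb, n),
    leads = snps
  )
}

test_that("signal similarity hits its closed forms", {
  pp <- make_pair_panels(5, 6, noise_sd = 0, seed = 2)
  sim <- signal_similarity(pp$panel_a, pp$panel_b, pp$leads, pp$leads)
  expect_equal(nrow(sim), 5)
  expect_equal(sim$r2, rep(1, 5), tolerance = 1e-12) # identical vectors
  expect_true(all(sim$same_snp))

  # global sign flip leaves the squared correlation at 1
  ppf <- make_pair_panels(5, 6, noise_sd = 0, seed = 2, flip = TRUE)
  simf <- signal_similarity(ppf$panel_a, ppf$panel_b, ppf$leads, ppf$leads)
  expect_equal(simf$r2, rep(1, 5), tolerance = 1e-12)

  # fewer than 3 shared traits is refused
  pp2 <- make_pair_panels(3, 2, noise_sd = 0, seed = 2)
  expect_error(
    signal_similarity(pp2$panel_a, pp2$panel_b, pp2$leads, pp2$leads),
    "3 shared traits"
  )
})

test_that("similarity median matches a Monte-Carlo oracle and degrades with divergence", {
  k <- 15; n_loci <- 100; noise_sd <- 0.8
  pp <- make_pair_panels(n_loci, k, noise_sd, seed = 5)
  sim <- signal_similarity(pp$panel_a, pp$panel_b, pp$leads, pp$leads)

  # independent Monte-Carlo oracle for the same generative model
  set.seed(900)
  oracle <- replicate(4000, {
    mu <- rnorm(k, sd = 4)
    cor(mu + rnorm(k, sd = noise_sd), mu + rnorm(k, sd = noise_sd))^2
  })
  expect_lt(abs(median(sim$r2) - median(oracle)), 0.02)
  expect_gt(median(sim$r2), 0.9) # shared effects concentrate near 1

  # per-ancestry effect perturbation degrades similarity continuously
  med <- vapply(c(0, 2, 6), function(s) {
    ppd <- make_pair_panels(n_loci, k, noise_sd, seed = 5, perturb_sd = s)
    median(signal_similarity(ppd$panel_a, ppd$panel_b, ppd$leads, ppd$leads)$r2)
  }, 1.0)
  expect_true(all(diff(med) < 0))
})

test_that("downsampling specificity is anchored at both ends of the sweep", {
  k <- 5
  traits <- paste0("t", seq_len(k))
  omega <- factor_omega(k, 0.4, traits = traits)
  # strong EUR leads in 6 bins; the comparison ancestry occupies 2 of them
  set.seed(77)
  z <- matrix(rnorm(6 * k, mean = 9), 6, k, dimnames = list(NULL, traits))
  snps <- tibble::tibble(
    rsid = paste0("lead", 1:6), chrom = "1", pos = as.integer(1:6 * 1e6 + 5)
  )
  panel <- z_panel(snps, z, stats::setNames(rep(5e5, k), traits))
  leads <- snps
  other <- tibble::tibble(chrom = "1", pos = as.integer(c(1e6 + 9, 3e6 + 9)))

  curve <- downsample_specificity(
    leads, panel, null_cov(omega), other, fractions = c(0, 0.5, 1)
  )
  # fraction 1: observed specificity = 4 exclusive bins / 6 detected
  expect_equal(curve$specificity[curve$fraction == 1], 4 / 6)
  expect_equal(curve$n_detected[curve$fraction == 1], 6)
  # fraction 0: no association survives
  expect_equal(curve$specificity[curve$fraction == 0], 0)
  expect_equal(curve$n_detected[curve$fraction == 0], 0)
})

test_that("matched simulated sample sizes dissolve specificity for equal effects", {
  # two ancestries with equal true effects but unequal N: at the matched
  # simulated N, formerly specific loci lose significance
  k <- 5
  traits <- paste0("t", seq_len(k))
  omega <- diag(k); dimnames(omega) <- list(traits, traits)
  gamma_row <- rep(0.008, k) # modest shared effect on every trait
  n_big <- 4e5; n_small <- 1e4
  set.seed(11)
  z_big <- sqrt(n_big) * gamma_row + rnorm(k) # clearly significant
  z_small <- sqrt(n_small) * gamma_row + rnorm(k) # not significant
  snps <- tibble::tibble(rsid = "lead1", chrom = "1", pos = 1500000L)
  panel_big <- z_panel(snps, matrix(z_big, 1, dimnames = list(NULL, traits)),
                       stats::setNames(rep(n_big, k), traits))
  # the small-N ancestry found nothing: no occupied bins
  other <- tibble::tibble(chrom = character(), pos = integer())

  curve <- downsample_specificity(
    snps, panel_big, null_cov(omega), other,
    fractions = c(n_small / n_big, 1)
  )
  expect_equal(curve$specificity[curve$fraction == 1], 1) # EUR-only locus
  # at the matched fraction the locus is no longer detected at all
  expect_equal(curve$n_detected[curve$fraction == n_small / n_big], 0)
})
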