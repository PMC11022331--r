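test_that("omnibus test matches chi-square closed forms", {
  # k = 1: T = z^2, chi-square_1 tail
  r1 <- omnibus_test(c(t1 = 2), null_cov(diag(1)))
  expect_equal(r1$statistic, 4)
  expect_equal(r1$df, 1)
  expect_equal(r1$p, 0.0455, tolerance = 1e-3)

  # worked 2x2 example: omega off-diagonal 0.5, z = (2, 2)
  om <- null_cov(matrix(c(1, .5, .5, 1), 2,
                        dimnames = list(c("a", "b"), c("a", "b"))))
  r2 <- omnibus_test(c(a = 2, b = 2), om)
  expect_equal(r2$statistic, 16 / 3, tolerance = 1e-12)
  expect_equal(r2$p, exp(-8 / 3), tolerance = 1e-12)
  expect_equal(r2$p, 0.0696, tolerance = 2e-3)

  # identity omega: T reduces to the sum of squares
  z <- c(x = 1.1, y = -0.4, w = 2.2)
  r3 <- omnibus_test(z, null_cov(diag(3) |> (\(m) {
    dimnames(m) <- list(names(z), names(z)); m
  })()))
  expect_equal(r3$statistic, sum(z^2))
})

test_that("omnibus is invariant to trait order and coherent sign flips", {
  om <- factor_omega(5, 0.6, traits = letters[1:5])
  z <- setNames(c(1.5, -2, 0.3, 4, -1), letters[1:5])
  base <- omnibus_test(z, null_cov(om))

  perm <- sample(letters[1:5])
  expect_equal(omnibus_test(z[perm], null_cov(om[perm, perm]))$statistic,
               base$statistic)

  # flip trait "b": negate its z and its omega row/column
  S <- diag(c(1, -1, 1, 1, 1))
  om_flip <- S %*% om %*% S
  dimnames(om_flip) <- dimnames(om)
  z_flip <- z; z_flip["b"] <- -z_flip["b"]
  expect_equal(omnibus_test(z_flip, null_cov(om_flip))$statistic, base$statistic)
})

test_that("masked traits reduce the degrees of freedom per SNP", {
  om <- null_cov(factor_omega(3, 0.4, traits = c("a", "b", "c")))
  r <- omnibus_test(c(a = 2, b = NA, c = 1), om)
  expect_equal(r$df, 2)
  sub <- om$omega[c("a", "c"), c("a", "c")]
  zz <- c(2, 1)
  expect_equal(r$statistic, sum(zz * solve(sub, zz)))
  expect_error(omnibus_test(c(a = NA_real_), null_cov(diag(1))), "masked")
})

test_that("scan agrees with the per-SNP test and handles missingness patterns", {
  traits <- c("a", "b", "c")
  om <- null_cov(factor_omega(3, 0.5, traits = traits))
  z <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, traits))
  z[3, 2] <- NA; z[7, c(1, 3)] <- NA
  snps <- tibble::tibble(rsid = paste0("rs", 1:10), chrom = "1", pos = 1:10 * 1000L)
  panel <- z_panel(snps, z, c(a = 1e4, b = 1e4, c = 1e4))
  scan <- omnibus_scan(panel, om)
  expect_equal(nrow(scan), 10)
  for (i in c(1, 3, 7)) {
    ref <- omnibus_test(z[i, ], om)
    row <- scan[scan$rsid == paste0("rs", i), ]
    expect_equal(row$statistic, ref$statistic)
    expect_equal(row$df, ref$df)
    expect_equal(row$log10p_joint, ref$log10p)
  }
})

test_that("trans-ancestry statistic sums chi-squares with summed df", {
  om1 <- null_cov(diag(1))
  # single ancestry: identical to the plain omnibus
  single <- trans_omnibus(list(list(z = c(t1 = 2), cov = om1)))
  plain <- omnibus_test(c(t1 = 2), om1)
  expect_equal(single$statistic, plain$statistic)
  expect_equal(single$p, plain$p)

  # two ancestries, each k = 1, z = 2: T = 8, df = 2, p = exp(-4)
  two <- trans_omnibus(list(
    list(z = c(t1 = 2), cov = om1), list(z = c(t1 = 2), cov = om1)
  ))
  expect_equal(two$statistic, 8)
  expect_equal(two$df, 2)
  expect_equal(two$p, exp(-4), tolerance = 1e-12)

  # four ancestries x 15 traits: df = 60
  om15 <- null_cov(factor_omega(15, 0.3))
  z15 <- setNames(rnorm(15), paste0("trait", 1:15))
  four <- trans_omnibus(rep(list(list(z = z15, cov = om15)), 4))
  expect_equal(four$df, 60)
  expect_error(trans_omnibus(list()), "empty")
})

test_that("trans scan restricts to the SNP intersection and adds statistics", {
  traits <- c("a", "b")
  om <- null_cov(diag(2) |> (\(m) {
    dimnames(m) <- list(traits, traits); m
  })())
  mk <- function(rsids, seed) {
    set.seed(seed)
    z_panel(
      tibble::tibble(rsid = rsids, chrom = "1",
                     pos = as.integer(sub("rs", "", rsids)) * 100L),
      matrix(rnorm(2 * length(rsids)), ncol = 2, dimnames = list(NULL, traits)),
      c(a = 1000, b = 1000)
    )
  }
  pA <- mk(paste0("rs", 1:8), 1)
  pB <- mk(paste0("rs", 5:12), 2)
  ts <- trans_scan(list(A = pA, B = pB), list(A = om, B = om))
  expect_equal(sort(ts$rsid), paste0("rs", 5:8))
  i <- match("rs6", pA$snps$rsid); j <- match("rs6", pB$snps$rsid)
  expect_equal(
    ts$statistic[ts$rsid == "rs6"],
    sum(pA$z[i, ]^2) + sum(pB$z[j, ]^2)
  )
  expect_equal(ts$df[ts$rsid == "rs6"], 4)
})

test_that("meta z-score is the sample-size-weighted fixed-effect combination", {
  expect_equal(meta_z(1.7, 5000), 1.7) # single ancestry unchanged
  expect_equal(meta_z(c(1, 1), c(1000, 1000)), sqrt(2), tolerance = 1e-12)
  expect_equal(meta_z(c(1, 2), c(100, 400)), (10 + 40) / sqrt(500), tolerance = 1e-12)
  # absent ancestries renormalize
  expect_equal(meta_z(c(1, NA, 2), c(100, 900, 400)), (10 + 40) / sqrt(500))
  expect_error(meta_z(c(NA, NA), c(1, 1)), "absent")
})

test_that("meta_panel applies meta_z across panels per trait", {
  traits <- "t1"
  mk <- function(rsids, z, n) {
    z_panel(
      tibble::tibble(rsid = rsids, chrom = "1",
                     pos = as.integer(sub("rs", "", rsids))),
      matrix(z, ncol = 1, dimnames = list(NULL, traits)), c(t1 = n)
    )
  }
  pa <- mk(c("rs1", "rs2"), c(1, 2), 100)
  pb <- mk(c("rs2", "rs3"), c(2, 3), 400)
  meta <- meta_panel(list(pa, pb))
  expect_equal(meta$z[meta$snps$rsid == "rs1", 1], c(t1 = 1))
  expect_equal(meta$z[meta$snps$rsid == "rs2", 1],
               c(t1 = (sqrt(100) * 2 + sqrt(400) * 2) / sqrt(500)))
  expect_equal(meta$n[["t1"]], 500)
})

test_that("z scaling to a simulated sample size is a square-root shrink", {
  expect_equal(scale_z(3, 1000, 1000), 3) # identity at full sample
  expect_equal(scale_z(3, 1000, 250), 1.5) # quarter sample halves z
  expect_equal(scale_z(3, 1000, 0), 0) # boundary of the 0-100% sweep
  expect_error(scale_z(3, 0, 0), "positive")
  expect_error(scale_z(3, 100, 200), "n_simulated")
})

test_that("minimum univariate p is uncorrected and tail-safe", {
  r <- min_univariate_p(c(a = 0, b = 1.96))
  expect_equal(r$p, 0.05, tolerance = 1e-3)
  expect_equal(r$trait, "b")

  expect_equal(min_univariate_p(c(only = 1.2))$p,
               2 * pnorm(-1.2), tolerance = 1e-12)

  # boundary of genome-wide significance, stable in log space
  r3 <- min_univariate_p(c(a = 5.45))
  expect_equal(r3$p, 5.0e-8, tolerance = 2e-2)
  # far tail: p underflows but log10p stays finite and exact
  r4 <- min_univariate_p(c(a = 40))
  expect_gt(r4$log10p, 300)
  expect_true(is.finite(r4$log10p))
})

test_that("genomic inflation is calibrated and scale-equivariant", {
  set.seed(2)
  stats <- rchisq(1e5, df = 15)
  expect_lt(abs(genomic_inflation(stats, 15) - 1), 0.02)
  expect_equal(genomic_inflation(2 * stats, 15),
               2 * genomic_inflation(stats, 15))
})

test_that("null omnibus type-I error is nominal at several thresholds", {
  traits <- paste0("trait", 1:15)
  omega <- factor_omega(15, 0.6)
  truth <- study_truth(
    matrix(0, 2e5, 15, dimnames = list(NULL, traits)),
    omega, setNames(rep(5e4, 15), traits)
  )
  ld <- make_ld_blocks(ld_spec(2e5, rep(1000, 200), decay = 0))
  panel <- simulate_z_panel(ld, truth, seed = 99)
  scan <- omnibus_scan(panel, null_cov(omega))
  p <- 10^(-scan$log10p_joint)
  for (alpha in c(0.05, 1e-4)) {
    hit <- mean(p < alpha)
    bound <- 4 * sqrt(alpha * (1 - alpha) / length(p))
    expect_lt(abs(hit - alpha), max(bound, 0.003))
  }
})

test_that("spreading an effect over correlated traits favors the joint test", {
  # effect split equally over 8 of 15 correlated traits at fixed N; compare
  # omnibus power with Bonferroni-corrected min-univariate power at 5e-4
  traits <- paste0("trait", 1:15)
  omega <- factor_omega(15, 0.6)
  delta <- 2 # expected z on each affected trait
  n_reps <- 4000
  gamma <- matrix(0, n_reps, 15, dimnames = list(NULL, traits))
  gamma[, 1:8] <- delta / sqrt(5e4)
  truth <- study_truth(gamma, omega, setNames(rep(5e4, 15), traits))
  ld <- make_ld_blocks(ld_spec(n_reps, rep(500, n_reps / 500), decay = 0))
  panel <- simulate_z_panel(ld, truth, seed = 77)
  scan <- omnibus_scan(panel, null_cov(omega))

  alpha <- 5e-4
  power_omni <- mean(scan$log10p_joint >= -log10(alpha))
  power_univ <- mean(scan$log10p_univ >= -log10(alpha / 15))
  expect_gt(power_omni, power_univ)
  expect_gt(power_omni - power_univ, 0.1)
})
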