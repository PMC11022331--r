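---
title: "Methods: multi-trait and trans-ancestry GWAS from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait and trans-ancestry GWAS from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointgwas)
```

This vignette is the package's own account of the statistical model it
implements, the assumptions behind each stage, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
more than one reasonable option existed.

## The omnibus model

A GWAS summary statistic for trait $t$ at a SNP is a z-score
$z_t = \hat\beta_t / \mathrm{se}(\hat\beta_t)$, standard normal under the
null of no association. Stacking the $k$ traits of a study into
$z = (z_1, \dots, z_k)$, the omnibus test statistic is the quadratic form

$$T = z^\top \Omega^{-1} z \sim \chi^2_k \quad \text{under } H_0,$$

where $\Omega$ is the covariance of $z$ at null SNPs. $\Omega$ is not the
identity because the per-trait GWAS share samples: for traits $i, j$
measured on cohorts of sizes $n_i, n_j$ with $n_s$ shared individuals and
total phenotypic covariance $\rho_{ij}$,

$$\Omega_{ij} = \rho_{ij} \frac{n_s}{\sqrt{n_i n_j}}.$$

Two limiting cases anchor intuition and the tests: with full overlap
($n_s = n_i = n_j$) $\Omega$ is exactly the Pearson correlation matrix of
the phenotypes, and with disjoint cohorts it is diagonal. The test assumes
an infinitesimal model in which, at a null SNP, the residual z-vector is
multivariate normal with this covariance.

The power argument for the joint test is geometric: a variant whose effect
is spread thinly over several correlated traits — or points in directions
*against* the phenotypic correlation — can have every univariate $|z_t|$
modest while $z^\top \Omega^{-1} z$ is large. The acceptance suite
demonstrates this mechanism: with an expected z of 2 on 8 of 15 correlated
traits, omnibus power at $\alpha = 5\times10^{-4}$ is about 0.7 against
about 0.11 for the Bonferroni-corrected best univariate test.

### Trans-ancestry extension

Cohorts of different ancestries are independent samples, so per-ancestry
omnibus statistics add:

$$T_\text{trans} = \sum_a z_a^\top \Omega_a^{-1} z_a \sim
  \chi^2\!\left(\sum_a k_a\right).$$

No homogeneity of effects across ancestries is assumed — each ancestry may
deviate from its null in its own direction, which is exactly what makes
the statistic robust to effect-size heterogeneity, at the price of
degrees of freedom. Trait counts may differ per ancestry ($k_a$), and the
scan is defined on the intersection of SNPs available in every ancestry.
The univariate comparator is the fixed-effect, sample-size-weighted
meta-analysis $Z_\text{meta} = \sum_a \sqrt{N_a} z_a / \sqrt{\sum_a N_a}$,
with weights renormalized over the ancestries where the SNP exists.

### Degrees-of-freedom adaptation

At SNPs where some traits are masked (absent from a study, or removed by
the sample-size filter), the masked traits are dropped and the reference
distribution becomes $\chi^2$ with the reduced $k$. The alternative —
filling zeros — would deflate the statistic and was rejected; the per-SNP
`df` column makes the adaptation visible in outputs.

## Estimating $\Omega$

When individual-level phenotypes are unavailable, $\Omega$ is estimated
from the summary statistics by LD-score regression: for each trait pair,
the per-SNP product $z_i z_j$ is regressed on the SNP's LD score (the sum
of $r^2$ to all SNPs within a 1000 kb window, computed by `ld_scores()`).
Polygenic signal scales with the LD score and loads on the slope; sample
overlap does not, and appears in the intercept, which therefore estimates
$\Omega_{ij}$. The diagonal comes from the same regression on $z_i^2$, and
is deliberately *not* forced to 1 so residual inflation is absorbed into
the null (a `unit_diagonal` flag restores strict semantics).

Implementation choices:

- Two-pass weighted least squares. The first pass is unweighted and
  supplies a variance model $\mathrm{var}(z_i z_j) \approx f_i f_j +
  f_{ij}^2$ (with $f$ the fitted expected products); the second pass
  weights by the reciprocal of that variance times the LD score (which
  discounts SNPs counted many times through their neighbors). This is the
  standard heteroskedasticity weighting of LD-score regression, written
  directly on sufficient statistics rather than through a model-fitting
  wrapper so the delete-one-block jackknife is cheap.
- Standard errors are a delete-one jackknife over 200 contiguous SNP
  blocks (the `n_blocks` default, conventional for genome-scale panels;
  tests at smaller panels use proportionally fewer blocks).
- The estimator requires spread in the LD scores: with constant scores the
  intercept is unidentified and the function fails loudly. This matters
  for simulated data — the generator's `decay` parameter accepts a
  per-block vector precisely so that simulated chromosomes have LD-score
  variation comparable to real panels.

On null synthetic panels of $10^5$ SNPs the intercepts recover a known
$\Omega$ with mean absolute error well under 0.01 (the acceptance script
measures it), comfortably within the 0.05 band the suite enforces; with
polygenic signal present the intercept remains accurate while the slope
absorbs the signal.

### Conditioning diagnostics

Nearly collinear traits combined with high sample overlap produce an
ill-conditioned $\Omega$; its inverse then amplifies small errors and the
omnibus statistic inflates wildly. `check_condition()` reports the ratio
of extreme eigenvalues and flags matrices above $10^4$ (a 2×2 matrix with
off-diagonal 0.9999 sits at $2\times10^4$; a realistic 15-trait matrix
with correlations up to 0.6 sits orders of magnitude below). The default
posture on a flagged matrix is to refuse and say why, mirroring the
practice of excluding such a trait set rather than silently repairing it;
`regularize()` — shrinkage $(1-\lambda)\Omega + \lambda I$ — is available
as an explicit, logged opt-in.

## Harmonization

`harmonize()` aligns per-trait records to a reference panel of common
variants: panel MAF must exceed 1%, alleles are oriented to the panel
(swapped effect/other alleles flip the sign of z; the flip conserves
$|z|$ exactly), and records whose alleles cannot be matched are dropped.
Decisions the data forced:

- **Strand-ambiguous SNPs (A/T, C/G) are dropped**, not rescued by
  frequency matching: a z-only pipeline carries no allele frequencies for
  the records, and a silent strand error flips the sign of a z-score —
  worse than losing the SNP.
- **Duplicated rsids keep the largest-n record**; the rest are logged.
- **Coordinates are 1-based** and reported as the panel gives them.
- **Sample-size harmonization**: within each trait, SNPs whose per-SNP n
  is below 70% of the trait's 90th-percentile n are masked. The 90th
  percentile (rather than the maximum) is robust to a few inflated n
  values; 0.7 removes sub-cohort variants whose z-scores are not
  exchangeable with the rest of the study while keeping minor n
  heterogeneity. The per-trait scalar N becomes the median n of retained
  SNPs. Setting the fraction to 0 disables the filter.

Harmonization is idempotent — running it on its own output changes
nothing — which the suite asserts.

## Imputation of untyped z-scores

Within an LD block with correlation matrix $\Sigma$, the conditional
expectation of an untyped SNP's z given typed neighbors is
$\hat z_u = \Sigma_{ut} \Sigma_{tt}^{-1} z_t$ with predicted quality
$r^2_u = \Sigma_{ut} \Sigma_{tt}^{-1} \Sigma_{tu}$ (clipped to $[0,1]$).
Three accuracy-control parameters gate the output, with defaults chosen
for high accuracy across traits and ancestries:

| parameter | default | role |
|---|---|---|
| `eigen_threshold` | 0.05 | eigenvalues of $\Sigma_{tt}$ below this fraction of the largest are truncated from the pseudo-inverse, stabilizing the solve among tightly linked typed SNPs; interpreted as *relative* to the largest eigenvalue |
| `r2_threshold` | 0.6 | untyped SNPs with predicted quality below this are left missing |
| `minimum_ld` | 5 | minimum count of *informative* typed neighbors, defined as $|r| > 0.2$ to the target |

With truncation disabled, `impute_block()` equals the exact dense solve to
$10^{-8}$ (asserted on 5–50 SNP blocks). Imputed entries carry an
`imputed` flag and their quality, so discovery can report imputed versus
typed leads. No variance re-inflation is applied to imputed z-scores; the
quality gate keeps $\mathrm{var}(\hat z_u)/r^2_u$ near 1 (checked within
10% in the suite), and the choice is recorded in the output metadata. On
synthetic blocks with adjacent-SNP correlation 0.95 and 20% of SNPs held
out, the imputed-versus-held-out correlation exceeds 0.9.

## LD-independent regions

`split_blocks()` partitions a chromosome into contiguous quasi-independent
blocks by minimizing the sum of squared correlations between SNPs in
different blocks, ignoring pairs with $r^2 <$ `thr_r2` (0.05), subject to
block sizes in `[min_size, max_size]` and at most `max_k` blocks. The
genome-scale presets (4000/5000/400) are defaults only; the dynamic
program is size-agnostic and exact: it enumerates, via prefix sums of the
thresholded $r^2$ matrix and a suffix-table DP, the optimal partition for
every feasible block count. Ties are resolved toward fewer blocks, then
earliest boundaries (the suffix formulation makes the front-to-back walk
yield the lexicographically earliest optimum). Intervals are half-open on
SNP indices; bp bounds are the first and last member SNP positions.
Infeasible size constraints fail with an explicit message rather than
being silently relaxed — the reference tooling's relaxation rules are not
documented, so none were invented.

## Discovery and novelty

The two-step procedure: LD-independent regions are scanned for a
genome-wide significant joint minimum ($p \le 5\times10^{-8}$); candidate
regions are clumped greedily — the smallest-p unassigned SNP with
$p \le$ `p1` ($5\times10^{-8}$) leads, unassigned SNPs with $p \le$ `p2`
($5\times10^{-4}$) and $r^2 \ge 0.2$ to the lead join, each SNP joining at
most one clump, ties on p broken by leftmost position (the reference
tool's tie behavior is unspecified; leftmost is deterministic and
order-independent). Clumps containing only their lead are discarded as
poor-quality signals. A lead is a **new** association when its joint
p-value is genome-wide significant while the minimum univariate p-value
across traits is not. The univariate minimum is deliberately uncorrected
for the number of traits — an inflation that makes the univariate
reference as generous as possible and the "new" label conservative. A
Bonferroni variant recomputes novelty at $5\times10^{-8}/m$ for $m$
analyses. All threshold comparisons happen in $-\log_{10}$ space, so
p-values below double-precision underflow ($10^{-300}$) remain ordered.

For trans-ancestry results, LD-independent regions are undefined across
ancestries, so leads are selected per fixed-origin 1 Mbp bin
($\lfloor (pos-1)/10^6 \rfloor$); positions 999,999 and 1,000,001 fall in
different bins by construction.

## Cross-ancestry comparison

`bin_loci()` marks a 1 Mbp bin detected in an ancestry if it contains any
significant association (joint or univariate) and reports UpSet-style
exclusive intersection counts, each flagged when a contributing
association was joint-only. `signal_similarity()` computes, per shared
bin, the squared Pearson correlation of the two ancestries' multi-trait
z-vectors over shared traits: the same variant is paired when it leads in
both ancestries, otherwise each ancestry's own lead (both modes exposed;
this default matches how lead pairs are usually displayed). Correlation on
z equals correlation on standardized effects because $\sqrt{N}$ is
constant within an ancestry. Traits absent from one ancestry are excluded
pairwise and at least three shared traits are required — a correlation
over two points is meaningless. Note $r^2$ is sign-insensitive: a global
sign flip of one ancestry's vector still gives $r^2 = 1$; divergence shows
up as a heavy lower tail of the per-locus distribution, not as a sign.

`downsample_specificity()` rescales one ancestry's lead z-scores by
$\sqrt{N_\text{sim}/N_\text{total}}$ (the exact behavior of a z-statistic
under a smaller sample at fixed effect size), recomputes joint and
univariate p-values at each fraction of a 0–100% sweep, and reports the
fraction of detected 1 Mbp loci that remain exclusive to that ancestry.
At fraction 1 this is the observed specificity; at fraction 0 nothing
survives. The detected-count curve should be non-decreasing in the
fraction; dips are reported rather than silently smoothed.

## The synthetic-data generator

`simulate_z_panel()` draws

$$Z = R\,\Gamma\,\mathrm{diag}(\sqrt{N}) + L_R\, E\, L_\Omega^\top,$$

with $R$ the block-diagonal LD matrix, $\Gamma$ standardized effects
(so $\sqrt{N}\gamma$ is the expected z — effects live on the z scale and
no allele-frequency bookkeeping is needed), and $L_R, L_\Omega$ symmetric
factors (Cholesky per LD block, eigenfactor for $\Omega$, which also
produces the explicit offending-eigenvalue error on an invalid $\Omega$).
The noise then has exactly the Kronecker covariance
$\Omega \otimes R$ — the minimal generative model consistent with the
omnibus null, and the suite verifies the empirical covariance entrywise
(30,000 replicates of a 10-SNP, 3-trait instance; at this replicate count
the sampling error of a covariance entry is about 0.008, so the 0.03
entrywise band is a sound check rather than a coin flip).

What it emulates: block LD with heterogeneous strength along the
chromosome; cross-trait residual covariance from sample overlap;
sparse pleiotropic effects shared or perturbed across ancestries
(`gamma_sd`); per-ancestry availability masks standing in for variants
rare or absent (MAF < 1%) in some ancestries; per-ancestry trait subsets.
What it does not: genotypes, coalescent or demographic realism, admixture
LD, allele-frequency-dependent architectures, in-sample LD estimation
noise. Passing tests therefore certify the statistical machinery under
the model's own assumptions, not robustness to real-data pathologies such
as mis-specified reference LD.

Seeds are explicit everywhere and one seed yields a bit-identical study;
internal stages derive child seeds deterministically so adding an
ancestry does not perturb another's draw.

## Problem sizes and study conditions

The calibration experiments run at $10^5$ SNPs: × 15 traits with
off-diagonals up to 0.6 for null calibration ($\lambda_{GC}$ within
[0.97, 1.03], type-I error at $\alpha = 0.05$ within ±0.005); four
ancestries with trait counts 15/15/13/15 for the trans-ancestry
$\chi^2_{58}$ Kolmogorov–Smirnov check (independent SNPs, so the KS
assumptions hold); $10^5$ SNPs in heterogeneous-decay blocks of 50 for
$\Omega$ recovery. The power experiment uses 4000 replicates of an effect
with expected z of 2 on 8 of 15 correlated traits — chosen from the
noncentral chi-square power curve as the regime where the joint test has
substantial power (≈0.7) while each univariate test is far from its
Bonferroni threshold. Oracle-equivalence checks (clumping, DP splitting,
imputation) run on ≤ 25–50 SNP instances where exhaustive references are
exact. The whole suite and the acceptance script each complete in a few
minutes on one CPU.

## Known limitations

- $\Omega$ estimated with error propagates into $T$; the jackknife SEs
  quantify the first but the test does not currently propagate them.
- The trans-ancestry scan requires the SNP intersection across ancestries,
  which can be small when coverage differs strongly.
- Clumping takes $r^2$ from the supplied (ancestry-matched) LD store;
  using a mismatched panel silently degrades clump quality.
- The LD-score regression needs a few thousand SNPs and LD-score spread;
  small or LD-flat panels are rejected rather than estimated badly.
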