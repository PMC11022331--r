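#' Parameters of the LD-block splitter
#'
#' Defaults are the genome-scale presets used for real reference panels
#' (thr_r2 = 0.05, blocks of 4000-5000 SNPs, at most 400 blocks per
#' chromosome); tests and small simulated chromosomes use scaled-down
#' values — the splitter is size-agnostic.
#'
#' @param thr_r2 Squared correlations below this floor are ignored in the
#'   cost; in `[0, 1)`.
#' @param min_size,max_size Allowed SNP count per block.
#' @param max_k Maximum number of blocks.
#' @return An object of class `block_split_params`.
#' @export
block_split_params <- function(thr_r2 = 0.05, min_size = 4000, max_size = 5000,
                               max_k = 400) {
  if (thr_r2 < 0 || thr_r2 >= 1) abort("thr_r2 must be in [0, 1).")
  if (min_size > max_size) abort("min_size must be <= max_size.")
  if (max_k < 1) abort("max_k must be >= 1.")
  structure(
    list(
      thr_r2 = thr_r2, min_size = as.integer(min_size),
      max_size = as.integer(max_size), max_k = as.integer(max_k)
    ),
    class = "block_split_params"
  )
}

# Accept either a dense correlation matrix or an ld_blocks object.
as_ld_matrix <- function(ld) {
  if (inherits(ld, "ld_blocks")) ld_as_matrix(ld) else {
    check_square_symmetric(ld, "ld")
  }
}

#' Per-SNP LD scores
#'
#' The LD score of SNP j is the sum of squared correlations with every SNP
#' within a physical window of it, including itself, so scores are always at
#' least 1. These are the regressors of LD-score regression.
#'
#' @param ld An `ld_blocks` object (SNPs in different blocks are
#'   uncorrelated).
#' @param window_kb Window half-width in kilobases (default 1000).
#' @return A tibble: rsid, chrom, pos, ld_score.
#' @export
ld_scores <- function(ld, window_kb = 1000) {
  stopifnot(inherits(ld, "ld_blocks"))
  window_bp <- window_kb * 1000
  pos <- ld$snps$pos
  score <- numeric(nrow(ld$snps))
  blocks <- ld_block_index(ld)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    r2 <- ld$matrices[[b]]^2
    in_window <- abs(outer(pos[idx], pos[idx], "-")) <= window_bp
    score[idx] <- rowSums(r2 * in_window)
  }
  ld$snps |>
    select("rsid", "chrom", "pos") |>
    mutate(ld_score = score)
}

# Upper-triangle cumulative sum of the thresholded r2 matrix; W(a, b) =
# within-[a, b] pair sum in O(1) per query.
thresholded_cumsum <- function(R, thr_r2) {
  t2 <- R^2
  t2[t2 < thr_r2] <- 0
  diag(t2) <- 0
  apply(apply(t2, 1, cumsum), 1, cumsum) # C[i, j] = sum rows<=i, cols<=j
}

pair_sum_within <- function(C, a, b) {
  tot <- C[b, b]
  if (a > 1) tot <- tot - C[a - 1, b] - C[b, a - 1] + C[a - 1, a - 1]
  tot / 2
}

#' Cost of a candidate block partition
#'
#' The splitting objective: the sum of squared correlations between SNPs
#' assigned to different blocks, counting only pairs with `r^2 >=
#' thr_r2`. A partition at the true boundaries of a block-diagonal matrix
#' has cost zero.
#'
#' @param ld Dense correlation matrix or `ld_blocks`.
#' @param ends Increasing integer vector of block end indices; the last must
#'   equal the SNP count (blocks are `[1..ends[1]]`, `(ends[1]..ends[2]]`,
#'   ...).
#' @param thr_r2 Squared-correlation floor (see [block_split_params()]).
#' @return The scalar cost.
#' @export
split_cost <- function(ld, ends, thr_r2 = 0.05) {
  R <- as_ld_matrix(ld)
  n <- nrow(R)
  ends <- as.integer(ends)
  if (is.unsorted(ends, strictly = TRUE) || tail(ends, 1) != n || any(ends < 1)) {
    abort("`ends` must be strictly increasing block end indices finishing at n.")
  }
  C <- thresholded_cumsum(R, thr_r2)
  total <- C[n, n] / 2
  starts <- c(1L, head(ends, -1) + 1L)
  within <- sum(map_dbl(seq_along(ends), function(b) {
    pair_sum_within(C, starts[b], ends[b])
  }))
  total - within
}

#' Split a correlation matrix into quasi-independent blocks
#'
#' Exact dynamic program over block boundaries: finds the partition of the
#' SNP index into contiguous blocks with sizes in `[min_size, max_size]` and
#' at most `max_k` blocks that minimizes [split_cost()]. Among equal-cost
#' solutions it prefers fewer blocks, then the earliest boundaries.
#'
#' @param ld Dense correlation matrix or `ld_blocks`; when an `ld_blocks` is
#'   given its SNP index supplies the chromosome and bp bounds.
#' @param params A [block_split_params()].
#' @return A `region_set`: a tibble with one row per block (region, start,
#'   end as half-open SNP indices, chrom, start_bp, end_bp, n_snps,
#'   cost_share) with the total cost and the parameters as attributes.
#' @export
split_blocks <- function(ld, params = block_split_params()) {
  R <- as_ld_matrix(ld)
  n <- nrow(R)
  if (n < params$min_size) abort("fewer SNPs than min_size.")
  b_lo <- ceiling(n / params$max_size)
  b_hi <- floor(n / params$min_size)
  if (b_lo > min(b_hi, params$max_k)) {
    abort(sprintf(
      "infeasible constraints: %d SNPs cannot be covered by <= %d blocks of %d-%d SNPs.",
      n, params$max_k, params$min_size, params$max_size
    ))
  }
  C <- thresholded_cumsum(R, params$thr_r2)
  total <- C[n, n] / 2
  kmax <- min(params$max_k, b_hi)

  # Suffix DP: h[i + 1, b + 1] = max within-block sum partitioning SNPs
  # (i..n] into exactly b legal blocks; walking it from the front yields the
  # lexicographically earliest optimal boundaries.
  h <- matrix(-Inf, n + 1, kmax + 1)
  h[n + 1, 1] <- 0
  for (i in (n - 1):0) {
    lo <- i + params$min_size
    hi <- min(i + params$max_size, n)
    if (lo > n) next
    for (b in 1:kmax) {
      best <- -Inf
      for (e in lo:hi) {
        prev <- h[e + 1, b]
        if (prev > -Inf) {
          v <- pair_sum_within(C, i + 1L, e) + prev
          if (v > best) best <- v
        }
      }
      h[i + 1, b + 1] <- best
    }
  }
  feasible_b <- which(h[1, -1] > -Inf)
  if (length(feasible_b) == 0) abort("no feasible partition under the size bounds.")
  costs <- total - h[1, feasible_b + 1]
  # Minimum cost; ties broken toward fewer blocks (feasible_b is increasing).
  b_star <- feasible_b[which(costs <= min(costs) + 1e-12)[1]]

  ends <- integer(b_star)
  i <- 0L
  for (b in b_star:1) {
    target <- h[i + 1, b + 1]
    for (e in (i + params$min_size):min(i + params$max_size, n)) {
      if (h[e + 1, b] > -Inf &&
          abs(pair_sum_within(C, i + 1L, e) + h[e + 1, b] - target) <= 1e-9) {
        ends[b_star - b + 1] <- e
        i <- e
        break
      }
    }
  }

  starts <- c(1L, head(ends, -1) + 1L)
  snps <- if (inherits(ld, "ld_blocks")) ld$snps else {
    tibble(chrom = "1", pos = seq_len(n))
  }
  out_cost <- total - h[1, b_star + 1]
  shares <- map_dbl(seq_along(ends), function(b) {
    # share of the total cost attributable to this block's outside pairs
    rect <- C[ends[b], n] - C[ends[b], ends[b]] -
      (if (starts[b] > 1) C[starts[b] - 1, n] - C[starts[b] - 1, ends[b]] else 0)
    rect
  })
  regions <- tibble(
    region = seq_along(ends),
    start = starts, end = ends + 1L, # half-open [start, end)
    chrom = snps$chrom[starts],
    start_bp = snps$pos[starts],
    end_bp = snps$pos[ends],
    n_snps = ends - starts + 1L,
    cost_share = if (out_cost > 0) shares / sum(shares) * out_cost else 0
  )
  structure(regions, class = c("region_set", class(regions)),
            cost = out_cost, params = params)
}

#' Total cost of a region set
#' @param regions A `region_set` from [split_blocks()].
#' @return Scalar cost.
#' @export
region_cost <- function(regions) attr(regions, "cost")

#' Assign SNPs to regions by position
#'
#' @param snps Tibble with chrom and pos columns.
#' @param regions A `region_set` (or any tibble with chrom, start_bp,
#'   end_bp, region).
#' @return `snps` with a `region` column; SNPs outside all regions get `NA`
#'   (and are reported).
#' @export
assign_regions <- function(snps, regions) {
  out <- snps |> mutate(.row = row_number())
  hit <- out |>
    inner_join(
      as_tibble(regions) |> select("region", "chrom", "start_bp", "end_bp"),
      by = "chrom", relationship = "many-to-many"
    ) |>
    filter(.data$pos >= .data$start_bp, .data$pos <= .data$end_bp) |>
    select(".row", "region")
  out <- out |> left_join(hit, by = ".row") |> select(-".row")
  n_out <- sum(is.na(out$region))
  if (n_out > 0) inform(sprintf("%d SNPs fall outside all regions.", n_out))
  out
}

#' Write a region set as a BED-like TSV
#' @param regions A `region_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path) {
  as_tibble(regions) |>
    select("chrom", "start_bp", "end_bp", "n_snps", "cost_share") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Persist an LD block store
#'
#' Writes each block's dense correlation matrix as a TSV plus an rsid
#' sidecar index, the format consumed by the imputation and clumping steps.
#'
#' @param ld An `ld_blocks` object.
#' @param dir Directory to create.
#' @return Invisibly, `dir`.
#' @export
write_ld_store <- function(ld, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(ld$snps, file.path(dir, "index.tsv"))
  blocks <- ld_block_index(ld)
  for (b in seq_along(blocks)) {
    utils::write.table(
      ld$matrices[[b]], file.path(dir, sprintf("block_%04d.tsv", b)),
      sep = "\t", row.names = FALSE, col.names = FALSE
    )
  }
  invisible(dir)
}

#' Read an LD block store written by [write_ld_store()]
#' @param dir Store directory.
#' @return An `ld_blocks` object.
#' @export
read_ld_store <- function(dir) {
  snps <- readr::read_tsv(file.path(dir, "index.tsv"),
    show_col_types = FALSE, progress = FALSE
  ) |> mutate(chrom = as.character(.data$chrom))
  files <- sort(list.files(dir, pattern = "^block_\\d+\\.tsv$", full.names = TRUE))
  mats <- map(files, function(f) {
    as.matrix(utils::read.table(f, sep = "\t"))
  })
  mats <- map(mats, function(m) {
    dimnames(m) <- NULL
    m
  })
  structure(list(snps = snps, matrices = mats), class = "ld_blocks")
}
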