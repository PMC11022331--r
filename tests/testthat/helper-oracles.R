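# Independent reference implementations used as oracles. Deliberately naive
# (double loops, exhaustive enumeration) and kept free of any package
# internals they are checking.

# LD score by direct double loop over SNP pairs of a dense matrix.
oracle_ld_scores <- function(R, pos, window_bp) {
  n <- nrow(R)
  sapply(seq_len(n), function(j) {
    s <- 0
    for (i in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= window_bp) s <- s + R[i, j]^2
    }
    s
  })
}

# Every partition of 1..n into contiguous blocks with sizes in
# [min_size, max_size] and at most max_k blocks, as vectors of end indices.
oracle_partitions <- function(n, min_size, max_size, max_k) {
  out <- list()
  recurse <- function(start, ends) {
    if (start > n) {
      if (length(ends) >= 1) out[[length(out) + 1]] <<- ends
      return(invisible())
    }
    if (length(ends) >= max_k) return(invisible())
    for (size in min_size:max_size) {
      e <- start + size - 1
      if (e > n) break
      recurse(e + 1, c(ends, e))
    }
  }
  recurse(1, integer(0))
  out
}

# Split cost by direct double loop.
oracle_split_cost <- function(R, ends, thr_r2) {
  n <- nrow(R)
  block_of <- rep(seq_along(ends), diff(c(0, ends)))
  cost <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (block_of[i] != block_of[j] && R[i, j]^2 >= thr_r2) {
        cost <- cost + R[i, j]^2
      }
    }
  }
  cost
}

# Greedy clumping re-implemented from its verbal description: smallest p
# first (leftmost on ties), members join the lead's clump when p <= p2 and
# r2 >= threshold, single assignment.
oracle_clump <- function(pvals, pos, r2_matrix, p1, p2, r2_min) {
  assignment <- rep(NA_integer_, length(pvals))
  leads <- integer(0)
  repeat {
    cand <- which(is.na(assignment) & pvals <= p1)
    if (length(cand) == 0) break
    cand <- cand[order(pvals[cand], pos[cand])]
    lead <- cand[1]
    leads <- c(leads, lead)
    members <- which(is.na(assignment) & pvals <= p2 &
                       r2_matrix[lead, ] >= r2_min)
    assignment[unique(c(lead, members))] <- length(leads)
  }
  list(assignment = assignment, leads = leads)
}

# Exact conditional-expectation imputation by a dense solve (no truncation).
oracle_impute <- function(z_typed, R, typed_index) {
  untyped <- setdiff(seq_len(nrow(R)), typed_index)
  S_tt <- R[typed_index, typed_index, drop = FALSE]
  S_ut <- R[untyped, typed_index, drop = FALSE]
  list(
    index = untyped,
    z = as.vector(S_ut %*% solve(S_tt, z_typed)),
    r2 = diag(S_ut %*% solve(S_tt, t(S_ut)))
  )
}

# Exchangeable-plus-factor positive-definite covariance with unit diagonal
# and off-diagonals up to `max_offdiag`, used as a study-condition Omega.
factor_omega <- function(k, max_offdiag = 0.6, traits = paste0("trait", seq_len(k))) {
  f <- seq(sqrt(0.25), 1, length.out = k)
  omega <- max_offdiag * outer(f, f)
  diag(omega) <- 1
  dimnames(omega) <- list(traits, traits)
  omega
}
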