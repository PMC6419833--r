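# Independent brute-force oracles shared across test files. These stay
# deliberately naive (explicit loops, exhaustive search) so they cannot
# share a bug with the vectorized implementations they check.

# Correlation over the upper triangle with optional co-zero exclusion.
oracle_correlation <- function(A, B, drop_cozero, min_entries = 3L) {
  a <- c(); b <- c()
  l <- nrow(A)
  for (i in seq_len(l - 1)) {
    for (j in (i + 1):l) {
      if (drop_cozero && A[i, j] == 0 && B[i, j] == 0) next
      a <- c(a, A[i, j]); b <- c(b, B[i, j])
    }
  }
  if (length(a) < min_entries) return(NA_real_)
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) return(NA_real_)
  sxy <- sum((a - mean(a)) * (b - mean(b)))
  sxx <- sum((a - mean(a))^2); syy <- sum((b - mean(b))^2)
  sxy / sqrt(sxx * syy)
}

# Append species whose rows/columns are zero in BOTH matrices.
augment_cozero <- function(m, k) {
  l <- nrow(m)
  out <- matrix(0, l + k, l + k)
  out[seq_len(l), seq_len(l)] <- m
  dimnames(out) <- list(paste0("x", seq_len(l + k)), paste0("x", seq_len(l + k)))
  out
}

# Exhaustive BH: check every candidate K directly.
oracle_bh <- function(p, alpha, strict = TRUE) {
  n <- length(p)
  ps <- sort(p)
  best <- 0L
  for (K in seq_len(n)) {
    lhs <- ps[K] * n
    rhs <- K * alpha
    tie <- abs(lhs - rhs) <= 1e-9 * max(abs(lhs), abs(rhs))
    ok <- if (strict) lhs < rhs && !tie else lhs < rhs || tie
    if (ok) best <- K
  }
  list(K = best, threshold = best * alpha / n)
}
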