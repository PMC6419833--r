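# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

# Random similarity-matrix pair from actual subalignments, so values are
# genuine match rates (rationals over the interval length).
rand_subalignment <- function(l = 5L, w = 12L, seed = 1L, p_absent = 0.2,
                              p_gap = 0.1) {
  set.seed(seed)
  panel <- sprintf("s%02d", seq_len(l))
  chars <- matrix(sample(c("A", "C", "G", "T"), l * w, replace = TRUE),
                  nrow = l, dimnames = list(panel, NULL))
  gap <- matrix(runif(l * w) < p_gap, nrow = l)
  chars[gap] <- "-"
  absent <- runif(l) < p_absent
  absent[1L] <- FALSE  # keep the reference present
  chars[absent, ] <- NA_character_
  list(interval = genomic_intervals("chr1", 0, w), panel = panel, chars = chars)
}

rand_simmat <- function(l = 5L, w = 12L, seed = 1L, ...) {
  build_similarity_matrix(rand_subalignment(l, w, seed, ...))
}

# Similarity matrix directly from an upper triangle (l = 3 panel),
# for the hand-computed sparse-correlation examples.
simmat_from_ut <- function(ut, diag = 1) {
  m <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  m[upper.tri(m)] <- ut
  m <- m + t(m)
  diag(m) <- diag
  m
}

# p-value catalog with a planted fraction of true tests (small-p Beta).
make_pvalue_catalog <- function(n, true_frac = 0.1, shape = 0.1, seed = 1L,
                                scores = NULL) {
  set.seed(seed)
  truth <- runif(n) < true_frac
  p <- runif(n)
  if (any(truth)) p[truth] <- rbeta(sum(truth), shape, 1)
  tab <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n)),
    gene_id = sprintf("gene%05d", seq_len(n)),
    nominal_p = p,
    stringsAsFactors = FALSE
  )
  if (!is.null(scores)) tab$score <- scores
  out <- hypothesis_catalog(tab)
  attr(out, "truth") <- truth
  out
}

# A small complete synthetic study used by several files (cached per
# session; ~1 s to build).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7L, genome_length = 60000L, n_snps = 40L,
                        n_genes = 12L, n_planted_pairs = 6L, matrix_flank = 80L)
      cache <<- list(config = cfg, study = simulate_eqtl_study(cfg))
    }
    cache
  }
})
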