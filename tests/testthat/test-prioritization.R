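test_that("the step-up rule finds the largest K with P_(K) < K alpha / n", {
  p <- c(0.001, 0.01, 0.03, 0.04, 0.2)
  fit <- bh_threshold(p, alpha = 0.05)
  expect_equal(fit$K, 2L)
  expect_equal(fit$threshold, 0.02)
  o <- oracle_bh(p, 0.05)
  expect_equal(fit$K, o$K)

  all0 <- bh_threshold(rep(0, 7), alpha = 0.05)
  expect_equal(all0$K, 7L)
  expect_equal(all0$threshold, 0.05)

  all1 <- bh_threshold(rep(1, 7), alpha = 0.05)
  expect_equal(all1$K, 0L)
  expect_equal(all1$threshold, 0)
  expect_length(all1$rejected, 0L)

  expect_error(bh_threshold(p, alpha = 0), "alpha")
  expect_error(bh_threshold(numeric(0)), "empty")
})

test_that("bh_threshold matches the exhaustive oracle on random catalogs", {
  set.seed(60)
  for (rep in 1:40) {
    n <- sample(1:20, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding creates ties
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    for (strict in c(TRUE, FALSE)) {
      fit <- bh_threshold(p, alpha, strict = strict)
      o <- oracle_bh(p, alpha, strict = strict)
      expect_equal(fit$K, o$K)
      expect_equal(fit$threshold, o$threshold)
      if (fit$K > 0) expect_true(all(p[fit$rejected] <= sort(p)[fit$K]))
    }
  }
})

test_that("strict rule never rejects more than <=, differing only on exact ties", {
  # engineered tie: P_(2) = 2 * 0.05 / 5 = 0.02 exactly
  p <- c(0.004, 0.02, 0.5, 0.6, 0.7)
  strict <- bh_threshold(p, 0.05, strict = TRUE)
  loose <- bh_threshold(p, 0.05, strict = FALSE)
  expect_equal(strict$K, 1L)
  expect_equal(loose$K, 2L)

  set.seed(61)
  for (rep in 1:30) {
    p <- round(runif(sample(3:25, 1)), 2)
    s <- bh_threshold(p, 0.05, strict = TRUE)
    l <- bh_threshold(p, 0.05, strict = FALSE)
    expect_lte(s$K, l$K)
    if (s$K != l$K) {
      ps <- sort(p)
      # they only diverge in the presence of ties P_(k) = k*alpha/n
      lhs <- ps * length(p); rhs <- seq_along(p) * 0.05
      expect_true(any(abs(lhs - rhs) <= 1e-9 * pmax(abs(lhs), abs(rhs))))
    }
    # the <= variant agrees with the standard adjusted-p formulation
    rej_adjust <- sum(p.adjust(p, "BH") <= 0.05)
    expect_equal(l$K, rej_adjust)
  }
})

test_that("FDR is controlled on fully-null catalogs", {
  false_rejections <- vapply(1:500, function(s) {
    set.seed(2000 + s)
    bh_threshold(runif(400), alpha = 0.05)$K > 0
  }, logical(1))
  # with all nulls, FDR = probability of any rejection <= alpha
  expect_lte(mean(false_rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("score prioritization retains defined scores above threshold and records gamma", {
  cat <- make_pvalue_catalog(100, seed = 3, scores = c(rep(0.9, 20), rep(0.1, 70),
                                                       rep(NA, 10)))
  sub <- prioritize_by_score(cat, 0.5)
  expect_equal(nrow(sub), 20L)
  expect_equal(attr(sub, "gamma"), 0.2)

  all_in <- prioritize_by_score(cat, -1)
  expect_equal(nrow(all_in), 90L)  # undefined scores are never retained
  expect_equal(attr(all_in, "gamma"), 0.9)

  none <- prioritize_by_score(cat, 2)
  expect_equal(nrow(none), 0L)
  expect_error(bh_threshold(none), "empty")

  cat$score <- NA_real_
  expect_error(prioritize_by_score(cat, 0.5), "undefined")
})

test_that("a threshold of -1 on fully scored tests reproduces plain BH", {
  cat <- make_pvalue_catalog(500, seed = 4, scores = runif(500))
  curve <- threshold_curve(cat, -1, alpha = 0.05)
  plain <- bh_threshold(cat, alpha = 0.05)
  expect_equal(curve$K, plain$K)
  expect_equal(curve$p_threshold, plain$threshold)
  expect_equal(curve$gamma, 1)
})

test_that("the enrichment identity P'/P = beta/gamma holds exactly by construction", {
  # 1000 tests: 100 clearly significant (tiny p), 900 clearly not (~1).
  # The prioritized subset keeps 50 of the significant and 150 others:
  # beta = 0.5, gamma = 0.2, so P'/P must be exactly 2.5.
  n <- 1000L
  p <- c(seq(1e-9, 1e-7, length.out = 100), seq(0.9, 1, length.out = 900))
  score <- c(rep(1, 50), rep(0, 50), rep(1, 150), rep(0, 750))
  cat <- hypothesis_catalog(data.frame(
    snp_id = sprintf("s%04d", 1:n), gene_id = sprintf("g%04d", 1:n),
    nominal_p = p, score = score
  ))
  full <- bh_threshold(cat, alpha = 0.05)
  expect_equal(full$K, 100L)
  sub <- prioritize_by_score(cat, 0.5)
  prio <- bh_threshold(sub, alpha = 0.05)
  expect_equal(prio$K, 50L)
  rep_ <- enrichment_ratio(full, prio)
  expect_equal(rep_$beta, 0.5)
  expect_equal(rep_$gamma, 0.2)
  expect_equal(rep_$ratio, 2.5)
  expect_lt(rep_$identity_gap, 1e-12)
})

test_that("prioritizing on a random score leaves the threshold unchanged on average", {
  ratios <- vapply(1:30, function(s) {
    cat <- make_pvalue_catalog(2000, true_frac = 0.1, seed = 5000 + s)
    set.seed(s)
    cat$score <- runif(2000)
    full <- bh_threshold(cat)
    sub <- prioritize_by_score(cat, 0.5)
    enrichment_ratio(full, bh_threshold(sub))$ratio
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se + 0.02)
})

test_that("random downsampling is seeded, bounded, and threshold-stable", {
  cat <- make_pvalue_catalog(20000, true_frac = 0.1, seed = 6)
  ident <- random_downsample(cat, 1, seed = 1)
  expect_equal(nrow(ident), 20000L)
  expect_equal(attr(ident, "parent_rows"), seq_len(20000))
  expect_equal(ident$nominal_p, cat$nominal_p)
  a <- random_downsample(cat, 0.1, seed = 2)
  b <- random_downsample(cat, 0.1, seed = 2)
  expect_identical(a, b)
  expect_equal(nrow(a), 2000L)
  expect_error(random_downsample(cat, 0), "fraction")
  expect_error(random_downsample(cat, 1.2), "fraction")

  full_thr <- bh_threshold(cat)$threshold
  rel <- vapply(1:50, function(s) {
    thr <- bh_threshold(random_downsample(cat, 0.1, seed = s))$threshold
    abs(thr - full_thr) / full_thr
  }, numeric(1))
  expect_lt(median(rel), 0.1)
})

test_that("distance matching selects the smallest-distance prefix deterministically", {
  cat <- make_pvalue_catalog(200, seed = 7)
  set.seed(7)
  cat$distance <- sample(1000:100000, 200)
  target <- mean(cat$distance)
  near_all <- distance_matched_subset(cat, target)
  expect_gte(nrow(near_all), 198L)  # the full-mean target keeps (nearly) all tests
  expect_lte(attr(near_all, "achieved_mean_distance"), target)

  tight <- distance_matched_subset(cat, min(cat$distance) + 1)
  expect_equal(nrow(tight), 1L)
  expect_equal(tight$distance, min(cat$distance))

  expect_error(distance_matched_subset(cat, min(cat$distance) - 1), "below the minimum")
})

test_that("score prioritization beats distance matching at matched mean distance", {
  # planted structure: true-eQTL probability decays with distance AND is
  # elevated for high-score pairs, so score prioritization carries
  # information beyond the distance reduction it causes
  wins <- vapply(1:20, function(s) {
    set.seed(7000 + s)
    n <- 4000L
    distance <- sample(1000:1000000, n, replace = TRUE)
    coevolved <- runif(n) < 0.1
    score <- ifelse(coevolved, runif(n, 0.75, 1), runif(n, -0.5, 0.75))
    p_true <- 0.02 + 0.08 * exp(-distance / 2e5) + 0.25 * coevolved
    truth <- runif(n) < p_true
    p <- ifelse(truth, rbeta(n, 0.1, 1), runif(n))
    cat <- hypothesis_catalog(data.frame(
      snp_id = sprintf("s%04d", 1:n), gene_id = sprintf("g%04d", 1:n),
      nominal_p = p, score = score
    ))
    cat$distance <- distance
    by_score <- prioritize_by_score(cat, 0.75)
    thr_score <- bh_threshold(by_score)$threshold
    by_dist <- distance_matched_subset(cat, mean(by_score$distance))
    thr_dist <- bh_threshold(by_dist)$threshold
    thr_score > thr_dist
  }, logical(1))
  expect_gt(mean(wins), 0.85)
})
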