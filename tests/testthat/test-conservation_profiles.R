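ramp_track <- function(n = 5000L) {
  # score at position i equals i: lets bin means be checked in closed form
  conservation_track(list(list(chrom = "chr1", start = 0L, values = as.numeric(0:(n - 1L)))))
}

test_that("profiles are 2001 long, strand-oriented, and missing-aware", {
  tr <- ramp_track()
  locus <- genomic_intervals("chr1", 2500L, 2501L, "+", "x")
  prof <- extract_profile(tr, locus)
  expect_length(prof, 2001L)
  expect_equal(as.numeric(prof), 1500:3500)
  expect_equal(as.numeric(prof)[1001], 2500)

  minus <- genomic_intervals("chr1", 2500L, 2501L, "-", "x")
  expect_equal(as.numeric(extract_profile(tr, minus)),
               rev(as.numeric(extract_profile(tr, locus))))

  # constant track: every entry equals the constant
  ct <- conservation_track(list(list(chrom = "chr1", start = 0L, values = rep(0.7, 5000))))
  expect_true(all(as.numeric(extract_profile(ct, locus)) == 0.7))

  # off-chromosome-start positions are missing, not zero
  edge <- genomic_intervals("chr1", 10L, 11L, "*", "e")
  pe <- as.numeric(extract_profile(tr, edge))
  expect_true(all(is.na(pe[1:990])))
  expect_equal(pe[991:1011], 0:20)

  wide <- genomic_intervals("chr1", 10L, 12L)
  expect_error(extract_profile(tr, wide), "width 1")
})

test_that("logarithmic binning reduces 2001 bases to 19 with the fixed layout", {
  sizes <- profile_bin_sizes()
  expect_length(sizes, 19L)
  expect_equal(sum(sizes), 2001L)
  expect_equal(sizes[10], 1L)
  expect_equal(sizes, rev(sizes))
  expect_equal(sizes[2:9], c(256L, 128L, 64L, 32L, 16L, 8L, 4L, 2L))

  bp <- bin_profile(rep(0.3, 2001))
  expect_length(bp$values, 19L)
  expect_true(all(bp$values == 0.3))

  expect_error(bin_profile(rep(0, 2000)), "2001")
})

test_that("bin means match a brute-force per-bin average", {
  x <- as.numeric(-1000:1000)      # score = relative position
  bp <- bin_profile(x)
  sizes <- profile_bin_sizes()
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  oracle <- vapply(seq_along(sizes), function(k) mean(x[starts[k]:ends[k]]), numeric(1))
  expect_equal(bp$values, oracle)

  set.seed(1)
  y <- rnorm(2001)
  bpy <- bin_profile(y)
  oracle_y <- vapply(seq_along(sizes), function(k) mean(y[starts[k]:ends[k]]), numeric(1))
  expect_equal(bpy$values, oracle_y)
  # bin-size-weighted mean of the binned profile equals the full-profile mean
  expect_equal(sum(bpy$values * sizes) / sum(sizes), mean(y))
  # profiles constant within each bin are reconstructed exactly
  z <- rep(oracle_y, sizes)
  expect_equal(bin_profile(z)$values, oracle_y)
})

test_that("missing bases are excluded from bin means, all-missing bins are NA", {
  x <- rep(1, 2001)
  x[1:490] <- NA             # entire outermost upstream bin
  x[491] <- NA               # one base of the next bin
  bp <- bin_profile(x)
  expect_true(is.na(bp$values[1]))
  expect_equal(bp$values[2], 1)  # remaining 255 observed bases average to 1
  expect_true(all(bp$values[3:19] == 1))
})

test_that("average pileup is the per-position mean with missing support", {
  set.seed(2)
  p1 <- rnorm(2001)
  expect_equal(average_pileup(matrix(p1, nrow = 1)), p1)
  expect_equal(average_pileup(rbind(p1, -p1)), rep(0, 2001))
  p2 <- p1; p2[5] <- NA
  expect_equal(average_pileup(rbind(p1, p2))[5], p1[5])
  expect_length(average_pileup(rbind(p1, p2), zoom = 100), 201L)
  expect_error(average_pileup(matrix(numeric(0), nrow = 0, ncol = 2001)), "at least one")
})

test_that("k-means recovers well-separated planted groups deterministically", {
  set.seed(3)
  a <- matrix(rnorm(30 * 19, 0, 0.1), ncol = 19)
  b <- matrix(rnorm(25 * 19, 2, 0.1), ncol = 19)
  x <- rbind(a, b)
  model <- kmeans_cluster(x, K = 2, seed = 9, restarts = 10)
  truth <- rep(1:2, c(30, 25))
  agreement <- max(mean(model$assignments == truth),
                   mean(model$assignments == 3 - truth))
  expect_equal(agreement, 1)

  model2 <- kmeans_cluster(x, K = 2, seed = 9, restarts = 10)
  expect_identical(model$centers, model2$centers)
  expect_identical(model$assignments, model2$assignments)

  # duplicating the data leaves the optimal centroids unchanged
  model_dup <- kmeans_cluster(rbind(x, x), K = 2, seed = 9, restarts = 10)
  ord1 <- order(rowMeans(model$centers))
  ord2 <- order(rowMeans(model_dup$centers))
  expect_equal(model_dup$centers[ord2, ], model$centers[ord1, ],
               ignore_attr = TRUE, tolerance = 1e-8)

  expect_error(kmeans_cluster(x[1, , drop = FALSE], K = 2), "at least K")
})

test_that("centroid labelling follows mean, then centre-bin tie-break", {
  model <- list(centers = rbind(rep(0, 19), rep(0.5, 19)), K = 2L)
  class(model) <- "cluster_model"
  out <- label_centroids(model)
  expect_equal(out$labels, c("low_conservation", "high_conservation"))

  # equal means: the centroid with the larger centre bin wins
  c1 <- rep(0.5, 19); c1[10] <- 0.2
  c2 <- rep(0.5, 19); c2[10] <- 0.8
  c1[1] <- 0.5 + (0.5 - 0.2); c2[1] <- 0.5 + (0.5 - 0.8)  # re-balance means
  model$centers <- rbind(c1, c2)
  expect_equal(unname(rowMeans(model$centers)[1]), unname(rowMeans(model$centers)[2]))
  out <- label_centroids(model)
  expect_equal(out$labels, c("low_conservation", "high_conservation"))

  model$K <- 3L
  expect_error(label_centroids(model), "K = 2")
})

test_that("the clustering pipeline recovers conservation classes on synthetic data", {
  st <- small_study()$study
  cfg <- small_study()$config
  profs <- extract_profiles(st$conservation$track, cfg$snps)
  binned <- bin_profiles(profs)
  model <- label_centroids(kmeans_cluster(binned, seed = 4))
  truth <- st$conservation$snp_labels[cfg$snps$name]
  expect_gt(mean(model$assignment_labels == unname(truth)), 0.9)
  # the high-conservation centroid has the conserved-flank shape:
  # positive flanks around a depressed centre
  hc <- model$centers[which(model$labels == "high_conservation"), ]
  expect_lt(hc[10], mean(hc[c(9, 11)]))
})

test_that("contingency tables count interactions and reproduce printed marginals", {
  tab <- contingency_from_counts(428, 7544, 1775, 40975)
  expect_equal(unname(tab$counts["HC", "HC"]), 428L)
  expect_equal(unname(tab$row_totals), c(7972L, 42750L))
  expect_equal(unname(tab$col_totals), c(2203L, 48519L))
  expect_equal(tab$total, 50722L)

  pairs <- data.frame(snp_id = c("s1", "s1", "s2"), gene_id = c("g1", "g2", "g1"))
  snp_labels <- c(s1 = "high_conservation", s2 = "low_conservation")
  gene_labels <- c(g1 = "high_conservation", g2 = "low_conservation")
  t2 <- contingency_table(pairs, snp_labels, gene_labels)
  # s1 appears in two interactions and is counted twice
  expect_equal(unname(t2$counts["HC", "HC"]), 1L)
  expect_equal(unname(t2$counts["LC", "HC"]), 1L)
  expect_equal(unname(t2$counts["HC", "LC"]), 1L)
  expect_equal(t2$total, 3L)

  expect_error(contingency_table(pairs, snp_labels[1], gene_labels), "s2")
})

test_that("Yates-corrected chi-squared matches the hand formula and reported values", {
  tab <- contingency_from_counts(428, 7544, 1775, 40975)
  fit <- chi_squared_yates(tab)
  expect_equal(round(fit$statistic, 3), 23.651)
  expect_equal(signif(fit$p_value, 4), 1.155e-6)

  # independent oracle: the corrected formula computed by hand
  O <- tab$counts
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  by_hand <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  expect_equal(fit$statistic, by_hand, tolerance = 1e-10)

  # without correction the statistic is ~23.94: the corrected form is
  # what reproduces the published value
  raw <- chi_squared_yates(tab, correct = FALSE)
  by_hand_raw <- sum((O - E)^2 / E)
  expect_equal(raw$statistic, by_hand_raw, tolerance = 1e-10)
  expect_equal(round(raw$statistic, 1), 23.9)

  # proportional table: observed = expected everywhere
  prop <- contingency_from_counts(10, 20, 30, 60)
  expect_equal(chi_squared_yates(prop, correct = FALSE)$statistic, 0)

  zero <- contingency_from_counts(0, 0, 3, 4)
  expect_error(chi_squared_yates(zero), "marginal")
})

test_that("continuity correction never exceeds the uncorrected statistic", {
  set.seed(8)
  for (i in 1:25) {
    cc <- contingency_from_counts(sample(1:50, 1), sample(1:50, 1),
                                  sample(1:50, 1), sample(1:50, 1))
    expect_lte(chi_squared_yates(cc, correct = TRUE)$statistic,
               chi_squared_yates(cc, correct = FALSE)$statistic + 1e-12)
  }
})

test_that("co-conservation dependence is detected with high power on planted tables", {
  # planted association: HC SNPs pair with HC genes more often than chance
  probs_dep <- c(hh = 0.10, hl = 0.15, lh = 0.15, ll = 0.60)
  rejections <- vapply(1:40, function(s) {
    set.seed(300 + s)
    cell <- sample(names(probs_dep), 4000, replace = TRUE, prob = probs_dep)
    n <- table(factor(cell, levels = names(probs_dep)))
    tab <- contingency_from_counts(n[["hh"]], n[["lh"]], n[["hl"]], n[["ll"]])
    chi_squared_yates(tab)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.95)
})

test_that("KS comparisons match a brute-force ECDF supremum and orient correctly", {
  x <- c(0, 0, 0); y <- c(1, 1)
  expect_equal(ks_compare(x, y)$D, 1)
  same <- c(0.1, 0.5, 0.9)
  r <- ks_compare(same, same)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)

  set.seed(10)
  a <- runif(1000); b <- runif(1000)
  grid <- sort(c(a, b))
  d_oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(ks_compare(a, b)$D, d_oracle, tolerance = 1e-8)

  # a is stochastically smaller than b: a_less is significant, a_greater is not
  b_shift <- b + 0.3
  expect_lt(ks_compare(a, b_shift, "a_less")$p, 1e-10)
  expect_gt(ks_compare(a, b_shift, "a_greater")$p, 0.5)

  expect_error(ks_compare(numeric(0), a), "non-empty")
})
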