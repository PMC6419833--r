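#' Cluster binned conservation profiles with k-means
#'
#' Euclidean k-means on the 19-dimensional binned profiles, keeping the
#' best of `restarts` seeded initializations by within-cluster sum of
#' squares. Missing bins are imputed by the profile's own mean before
#' clustering (a profile with no observed bin is rejected). With the
#' default K = 2 the two centroids separate the flat, near-neutral
#' profiles from the conserved ones.
#'
#' @param binned Matrix of binned profiles (rows = loci, 19 columns).
#' @param K Number of centroids (default 2).
#' @param seed RNG seed making the restarts reproducible.
#' @param restarts Number of random initializations (default 10).
#' @return A list of class `cluster_model`: `centers` (K x 19),
#'   `assignments` (integer per profile), `withinss_total`, `K`,
#'   `seed`, `restarts`, and `labels` (filled by [label_centroids()]).
#' @export
kmeans_cluster <- function(binned, K = 2L, seed = 1L, restarts = 10L) {
  if (is.null(dim(binned))) binned <- matrix(binned, nrow = 1L)
  if (nrow(binned) < K) stop("need at least K profiles to fit K centroids")
  empty <- apply(binned, 1L, function(r) all(is.na(r)))
  if (any(empty)) stop("profiles with no observed bin cannot be clustered: rows ",
                       paste(which(empty), collapse = ", "))
  imputed <- t(apply(binned, 1L, function(r) {
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    r
  }))
  set.seed(seed)
  fit <- stats::kmeans(imputed, centers = K, nstart = restarts, iter.max = 100L)
  structure(list(
    centers = fit$centers,
    assignments = fit$cluster,
    withinss_total = fit$tot.withinss,
    K = K, seed = seed, restarts = restarts,
    labels = NULL
  ), class = "cluster_model")
}

#' Label the two centroids as high/low conservation
#'
#' The centroid with the larger mean over its 19 bin values is the
#' high-conservation centroid; ties are broken by the centre-bin value,
#' then by centroid index (deterministic).
#'
#' @param model A K = 2 [kmeans_cluster()] model.
#' @return The model with `labels`: character vector of length 2 giving
#'   `"high_conservation"` / `"low_conservation"` per centroid, and
#'   `assignment_labels` per profile.
#' @export
label_centroids <- function(model) {
  if (model$K != 2L) stop("centroid labelling is defined for K = 2 only")
  means <- rowMeans(model$centers)
  centre_col <- (ncol(model$centers) + 1L) %/% 2L
  centre <- model$centers[, centre_col]
  ord <- order(-means, -centre, seq_along(means))
  labels <- character(2L)
  labels[ord[1L]] <- "high_conservation"
  labels[ord[2L]] <- "low_conservation"
  model$labels <- labels
  model$assignment_labels <- labels[model$assignments]
  names(model$assignment_labels) <- names(model$assignments)
  model
}

#' Co-conservation contingency table of eQTL interactions
#'
#' Cross-tabulates interactions (not unique loci: a SNP or gene in
#' several pairs is counted once per pair) by the conservation class of
#' the SNP and of the target gene.
#'
#' @param pairs Data.frame with `snp_id` and `gene_id` columns.
#' @param snp_labels Named character vector mapping SNP ids to
#'   `"high_conservation"` / `"low_conservation"`.
#' @param gene_labels Same for gene ids.
#' @return A list of class `contingency_2x2`: `counts` (2 x 2 matrix,
#'   rows = target-gene class HC/LC, columns = SNP class HC/LC),
#'   `row_totals`, `col_totals`, `total`.
#' @export
contingency_table <- function(pairs, snp_labels, gene_labels) {
  lv <- c("high_conservation", "low_conservation")
  sl <- snp_labels[pairs$snp_id]
  gl <- gene_labels[pairs$gene_id]
  bad <- unique(c(pairs$snp_id[is.na(sl)], pairs$gene_id[is.na(gl)]))
  if (length(bad) > 0L) {
    stop("unlabeled catalog members: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(gl, levels = lv), factor(sl, levels = lv))
  counts <- matrix(as.integer(counts), 2L, 2L,
                   dimnames = list(target = c("HC", "LC"), snp = c("HC", "LC")))
  structure(list(
    counts = counts,
    row_totals = rowSums(counts),
    col_totals = colSums(counts),
    total = sum(counts)
  ), class = "contingency_2x2")
}

#' Build a contingency table directly from counts
#'
#' @param a,b,c,d Counts for (HC SNP, HC target), (LC SNP, HC target),
#'   (HC SNP, LC target), (LC SNP, LC target).
#' @return A `contingency_2x2` object.
#' @export
contingency_from_counts <- function(a, b, c, d) {
  counts <- matrix(as.integer(c(a, c, b, d)), 2L, 2L,
                   dimnames = list(target = c("HC", "LC"), snp = c("HC", "LC")))
  structure(list(
    counts = counts,
    row_totals = rowSums(counts),
    col_totals = colSums(counts),
    total = sum(counts)
  ), class = "contingency_2x2")
}

#' Chi-squared test of a 2x2 co-conservation table
#'
#' Pearson chi-squared with Yates continuity correction by default
#' (each cell contributes `(max(|O-E| - 0.5, 0))^2 / E`); df = 1.
#'
#' @param table A `contingency_2x2` object.
#' @param correct Apply the continuity correction (default TRUE).
#' @return List of class `chisq_result`: `statistic`, `p_value`,
#'   `corrected`, `df`.
#' @export
chi_squared_yates <- function(table, correct = TRUE) {
  counts <- table$counts
  if (sum(counts) <= 0L) stop("empty contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) stop("zero marginal: expected counts undefined")
  fit <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(
    statistic = unname(fit$statistic),
    p_value = unname(fit$p.value),
    corrected = correct,
    df = unname(fit$parameter)
  ), class = "chisq_result")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the distributions of two score samples. One-sided
#' alternatives are expressed in terms of the *values*: `"a_less"`
#' tests whether `sample_a` is stochastically smaller than `sample_b`
#' (its ECDF lies above), `"a_greater"` the reverse.
#'
#' @param sample_a,sample_b Numeric samples (non-empty; NAs dropped).
#' @param alternative One of `"two_sided"`, `"a_less"`, `"a_greater"`.
#' @return List with `D` (the relevant supremum statistic) and `p`.
#' @export
ks_compare <- function(sample_a, sample_b,
                       alternative = c("two_sided", "a_less", "a_greater")) {
  alternative <- match.arg(alternative)
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("ks_compare requires non-empty samples")
  }
  # stats::ks.test's "greater" is D+ = sup(ECDF_a - ECDF_b), i.e. a
  # stochastically smaller than b; map value-based alternatives onto it.
  alt <- switch(alternative,
                two_sided = "two.sided",
                a_less = "greater",
                a_greater = "less")
  fit <- suppressWarnings(stats::ks.test(sample_a, sample_b, alternative = alt))
  list(D = unname(fit$statistic), p = unname(fit$p.value))
}
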