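#' Benjamini-Hochberg step-up significance threshold
#'
#' Sorts the catalog's nominal p-values ascending and finds the largest
#' K such that `P_(K) < K * alpha / n` (strict inequality by default;
#' `strict = FALSE` gives the conventional `<=` variant, which can
#' differ only on exact ties `P_(K) = K alpha / n`). The K smallest
#' hypotheses are rejected and the significance threshold reported is
#' `P = K alpha / n` (0 when nothing is rejected).
#'
#' @param catalog A `hypothesis_catalog` data.frame (needs `nominal_p`)
#'   or a bare numeric vector of p-values.
#' @param alpha Target false discovery rate, in (0, 1); default 0.05.
#' @param strict Use the strict `<` rule (default TRUE).
#' @return List of class `bh_result`: `alpha`, `n_tests`, `K`,
#'   `threshold` (= K alpha / n), `rejected` (row indices into the
#'   catalog, ordered by p), `catalog`.
#' @export
bh_threshold <- function(catalog, alpha = 0.05, strict = TRUE) {
  if (is.numeric(catalog)) {
    if (length(catalog) == 0L) stop("empty hypothesis catalog")
    catalog <- hypothesis_catalog(data.frame(
      snp_id = NA_character_, gene_id = NA_character_, nominal_p = catalog
    ))
  }
  p <- catalog$nominal_p
  n <- length(p)
  if (n == 0L) stop("empty hypothesis catalog")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  ord <- order(p)
  # decimal p-values and cutoffs K*alpha/n are not exactly representable,
  # so an intended tie P_(K) = K*alpha/n can differ by a few ulp in either
  # direction; values within 1e-9 relative are treated as tied, which is
  # where the strict-< and conventional-<= rules are meant to diverge
  lhs <- p[ord] * n
  rhs <- seq_len(n) * alpha
  tie <- abs(lhs - rhs) <= 1e-9 * pmax(abs(lhs), abs(rhs))
  ok <- if (strict) lhs < rhs & !tie else lhs < rhs | tie
  K <- if (any(ok)) max(which(ok)) else 0L
  structure(list(
    alpha = alpha, n_tests = n, K = K,
    threshold = K * alpha / n,
    rejected = if (K > 0L) ord[seq_len(K)] else integer(),
    strict = strict,
    catalog = catalog
  ), class = "bh_result")
}

#' Retain hypotheses above a coevolution-score threshold
#'
#' Prioritization keeps the tests whose coevolution score is defined
#' and at least `score_threshold`; tests with undefined scores are
#' never retained (prioritization is only defined where the score is).
#' The retained fraction of all hypotheses is gamma.
#'
#' @param catalog A `hypothesis_catalog` with a `score` column.
#' @param score_threshold Minimum score retained.
#' @return The retained sub-catalog with attributes `gamma` and
#'   `parent_rows` (row indices into `catalog`).
#' @export
prioritize_by_score <- function(catalog, score_threshold) {
  if (is.null(catalog$score)) stop("catalog has no score column")
  if (all(is.na(catalog$score))) stop("all coevolution scores are undefined")
  keep <- which(!is.na(catalog$score) & catalog$score >= score_threshold)
  out <- catalog[keep, , drop = FALSE]
  attr(out, "gamma") <- length(keep) / nrow(catalog)
  attr(out, "parent_rows") <- keep
  out
}

#' Significance-threshold curve over coevolution-score thresholds
#'
#' For each score threshold, runs BH independently on the retained
#' subset and records the retained fraction gamma, the number of
#' rejections K, and the relaxed significance threshold P'. Rows where
#' the retained subset is empty are flagged and carry NA results.
#'
#' @param catalog A `hypothesis_catalog` with `score` and `nominal_p`.
#' @param score_thresholds Numeric vector of thresholds (>= 1 value).
#' @param alpha FDR level for each BH run.
#' @param strict Passed to [bh_threshold()].
#' @return Data.frame: `score_threshold`, `n_retained`, `gamma`, `K`,
#'   `p_threshold`, `empty`.
#' @export
threshold_curve <- function(catalog, score_thresholds, alpha = 0.05, strict = TRUE) {
  if (length(score_thresholds) < 1L) stop("need at least one score threshold")
  rows <- lapply(score_thresholds, function(t) {
    sub <- prioritize_by_score(catalog, t)
    if (nrow(sub) == 0L) {
      return(data.frame(score_threshold = t, n_retained = 0L, gamma = 0,
                        K = NA_integer_, p_threshold = NA_real_, empty = TRUE))
    }
    fit <- bh_threshold(sub, alpha = alpha, strict = strict)
    data.frame(score_threshold = t, n_retained = nrow(sub),
               gamma = attr(sub, "gamma"), K = fit$K,
               p_threshold = fit$threshold, empty = FALSE)
  })
  do.call(rbind, rows)
}

#' Enrichment report: threshold relaxation and the beta/gamma identity
#'
#' Prioritizing the catalog relaxes the BH significance threshold from
#' P = K alpha / n to P' = beta K alpha / (gamma n), where beta is the
#' fraction of the full catalog's significant tests that survive the
#' prioritization and gamma the fraction of all tests that do. Whenever
#' beta > gamma the threshold is relaxed, and P'/P = beta/gamma, so the
#' threshold ratio measures the enrichment of the prioritized set for
#' significant interactions.
#'
#' @param full A [bh_threshold()] result on the full catalog.
#' @param prioritized A [bh_threshold()] result on a sub-catalog
#'   produced by [prioritize_by_score()] (or any subset carrying a
#'   `parent_rows` attribute on its catalog rows).
#' @param parent_rows Row indices of the prioritized catalog within the
#'   full catalog; defaults to the sub-catalog's `parent_rows`
#'   attribute.
#' @return List of class `enrichment_report`: `P`, `P_prime`, `ratio`
#'   (P'/P; NA when K = 0 in the full result), `beta`, `gamma`,
#'   `identity_gap` (|P'/P - beta/gamma|).
#' @export
enrichment_ratio <- function(full, prioritized, parent_rows = NULL) {
  if (is.null(parent_rows)) parent_rows <- attr(prioritized$catalog, "parent_rows")
  if (is.null(parent_rows)) {
    stop("parent_rows not available: prioritized result must come from a prioritize_by_score subset")
  }
  P <- full$threshold
  P_prime <- prioritized$threshold
  gamma <- length(parent_rows) / full$n_tests
  beta <- if (full$K > 0L) {
    length(intersect(full$rejected, parent_rows)) / full$K
  } else {
    NA_real_
  }
  ratio <- if (full$K > 0L) P_prime / P else NA_real_
  identity_gap <- if (!is.na(ratio) && !is.na(beta) && gamma > 0) {
    abs(ratio - beta / gamma)
  } else {
    NA_real_
  }
  structure(list(P = P, P_prime = P_prime, ratio = ratio,
                 beta = beta, gamma = gamma, identity_gap = identity_gap),
            class = "enrichment_report")
}

#' Random downsampling control
#'
#' Uniform seeded subsample of the catalog without replacement — the
#' control showing that merely reducing the number of tests leaves the
#' BH threshold essentially unchanged (unlike score-based
#' prioritization, which shifts it).
#'
#' @param catalog A `hypothesis_catalog`.
#' @param fraction Fraction of rows kept, in (0, 1].
#' @param seed RNG seed.
#' @return The subsampled catalog with a `parent_rows` attribute.
#' @export
random_downsample <- function(catalog, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  n <- nrow(catalog)
  if (fraction == 1) {
    keep <- seq_len(n)
  } else {
    set.seed(seed)
    keep <- sort(sample.int(n, size = round(fraction * n)))
  }
  out <- catalog[keep, , drop = FALSE]
  attr(out, "parent_rows") <- keep
  out
}

#' Distance-matched prioritization control
#'
#' Score-based prioritization also shortens the average SNP-gene
#' distance of the retained tests; this control isolates that side
#' effect by selecting on distance alone. The rule is deterministic:
#' take the tests in increasing distance order and keep the largest
#' prefix whose mean distance does not exceed the target.
#'
#' @param catalog A `hypothesis_catalog` with defined `distance`.
#' @param target_mean_distance Target average distance (e.g. the mean
#'   distance of a score-prioritized subset).
#' @return The retained sub-catalog with attributes `parent_rows` and
#'   `achieved_mean_distance`.
#' @export
distance_matched_subset <- function(catalog, target_mean_distance) {
  d <- catalog$distance
  if (is.null(d) || any(is.na(d))) stop("all pair distances must be defined (cis pairs)")
  if (target_mean_distance < min(d)) {
    stop("target mean distance is below the minimum pair distance")
  }
  ord <- order(d)
  prefix_mean <- cumsum(d[ord]) / seq_along(ord)
  k <- max(which(prefix_mean <= target_mean_distance))
  keep <- sort(ord[seq_len(k)])
  out <- catalog[keep, , drop = FALSE]
  attr(out, "parent_rows") <- keep
  attr(out, "achieved_mean_distance") <- mean(d[keep])
  out
}
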