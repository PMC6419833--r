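#' Sparse correlation of two similarity matrices
#'
#' The coevolution score of two genomic intervals: the product-moment
#' correlation of their similarity matrices over the off-diagonal upper
#' triangle, *after dropping every entry pair where both matrices are
#' exactly 0*. Shared zeros arise from shared missing alignments and
#' would otherwise inflate the correlation (the motivation for using
#' sparse rather than full correlation); exact equality to 0 is the
#' right test because match rates are rational counts over the interval
#' length. The score is undefined when fewer than `min_entries` entry
#' pairs remain or a retained vector has zero variance.
#'
#' @param A,B Similarity matrices over the same species panel.
#' @param min_entries Minimum retained entry pairs for a defined score
#'   (default 3; two points always correlate perfectly).
#' @return List of class `coevolution_score`: `value` (in \[-1, 1\], or
#'   `NA` if undefined), `n_retained`, `undefined_reason` (one of
#'   `"none"`, `"too_few_entries"`, `"zero_variance"`).
#' @export
sparse_correlation <- function(A, B, min_entries = 3L) {
  .matrix_correlation(A, B, drop_cozero = TRUE, min_entries = min_entries)
}

#' Full (classical mirrortree) correlation of two similarity matrices
#'
#' As [sparse_correlation()] but without the co-zero exclusion: every
#' off-diagonal upper-triangle entry pair enters the correlation. Kept
#' for comparison; inflates when both intervals share many missing
#' alignments.
#'
#' @inheritParams sparse_correlation
#' @return A `coevolution_score` list.
#' @export
full_correlation <- function(A, B, min_entries = 3L) {
  .matrix_correlation(A, B, drop_cozero = FALSE, min_entries = min_entries)
}

.matrix_correlation <- function(A, B, drop_cozero, min_entries) {
  if (!identical(dim(A), dim(B))) stop("similarity matrices must share the species panel")
  if (!is.null(dimnames(A)) && !is.null(dimnames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("similarity matrices must share the species panel (order included)")
  }
  ut <- upper.tri(A)
  a <- A[ut]
  b <- B[ut]
  if (drop_cozero) {
    keep <- !(a == 0 & b == 0)
    a <- a[keep]
    b <- b[keep]
  }
  n <- length(a)
  score <- function(value, reason) {
    structure(list(value = value, n_retained = n, undefined_reason = reason),
              class = "coevolution_score")
  }
  if (n < min_entries) return(score(NA_real_, "too_few_entries"))
  if (stats::var(a) == 0 || stats::var(b) == 0) return(score(NA_real_, "zero_variance"))
  score(stats::cor(a, b), "none")
}

#' Score coevolution for a catalog of SNP-gene pairs
#'
#' One sparse-correlation score per listed pair, or — in all-pairs mode
#' — for every SNP x gene combination (the bipartite extension of
#' mirrortree to two distinct locus sets). Runtime is O(n l^2) for n
#' scored pairs with an l-species panel.
#'
#' @param snp_matrices Named list of similarity matrices for SNP loci.
#' @param gene_matrices Named list for gene loci (TSS windows).
#' @param catalog Data.frame with `snp_id`, `gene_id` columns; ignored
#'   when `all_pairs = TRUE`.
#' @param all_pairs Score every combination instead of listed pairs.
#' @param min_entries Passed to [sparse_correlation()].
#' @return Data.frame: `snp_id`, `gene_id`, `score`, `n_retained`,
#'   `undefined_reason`.
#' @export
score_pairs <- function(snp_matrices, gene_matrices, catalog = NULL,
                        all_pairs = FALSE, min_entries = 3L) {
  if (all_pairs) {
    combos <- expand.grid(snp_id = names(snp_matrices), gene_id = names(gene_matrices),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    if (is.null(catalog)) stop("either a catalog or all_pairs = TRUE is required")
    combos <- catalog[, c("snp_id", "gene_id")]
    missing_snp <- setdiff(unique(combos$snp_id), names(snp_matrices))
    missing_gene <- setdiff(unique(combos$gene_id), names(gene_matrices))
    if (length(missing_snp) + length(missing_gene) > 0L) {
      stop("loci without similarity matrices: ",
           paste(c(missing_snp, missing_gene), collapse = ", "))
    }
  }
  n <- nrow(combos)
  score <- numeric(n)
  n_retained <- integer(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    s <- sparse_correlation(snp_matrices[[combos$snp_id[i]]],
                            gene_matrices[[combos$gene_id[i]]],
                            min_entries = min_entries)
    score[i] <- s$value
    n_retained[i] <- s$n_retained
    reason[i] <- s$undefined_reason
  }
  data.frame(snp_id = combos$snp_id, gene_id = combos$gene_id,
             score = score, n_retained = n_retained, undefined_reason = reason,
             stringsAsFactors = FALSE)
}

#' Coevolution of a SNP with a gene's promoters (max rule)
#'
#' Genes often have several annotated promoters; assuming an eQTL acts
#' through a single one, the SNP-promoter coevolution score of a gene
#' is the maximum over its promoters' defined scores. Undefined only if
#' every per-promoter score is undefined.
#'
#' @param snp_matrix Similarity matrix of the SNP locus.
#' @param promoter_matrices Non-empty list of similarity matrices, one
#'   per promoter of the gene.
#' @param min_entries Passed to [sparse_correlation()].
#' @return A `coevolution_score` list; `n_retained` is taken from the
#'   winning promoter.
#' @export
promoter_max_score <- function(snp_matrix, promoter_matrices, min_entries = 3L) {
  if (length(promoter_matrices) == 0L) stop("gene has no promoter matrices")
  scores <- lapply(promoter_matrices, function(P) {
    sparse_correlation(snp_matrix, P, min_entries = min_entries)
  })
  vals <- vapply(scores, function(s) s$value, numeric(1))
  if (all(is.na(vals))) {
    return(structure(list(value = NA_real_, n_retained = 0L,
                          undefined_reason = "all_promoters_undefined"),
                     class = "coevolution_score"))
  }
  scores[[which.max(vals)]]
}

#' Background coevolution score distribution
#'
#' Scores all SNP x gene combinations (or, in `promoter_max` mode, the
#' max-over-promoters score per SNP-gene combination) to form the
#' null/background distribution against which the eQTL pairs' scores
#' are compared. When the number of combinations exceeds `budget`, a
#' seeded uniform subsample of combinations is scored instead —
#' refusing unless `subsample = TRUE` makes the truncation explicit.
#' Undefined scores are excluded from the histogram and reported by
#' count.
#'
#' @param snp_matrices Named list of SNP similarity matrices.
#' @param gene_matrices Named list of gene (TSS) matrices, or — in
#'   `promoter_max` mode — a named list of *lists* of promoter
#'   matrices per gene.
#' @param mode `"gene"` or `"promoter_max"`.
#' @param budget Maximum number of combinations scored directly.
#' @param subsample Allow seeded subsampling past the budget.
#' @param seed Subsampling seed.
#' @param breaks Histogram bin edges over \[-1, 1\].
#' @return List: `scores` (defined scores), `n_undefined`, `histogram`
#'   (counts per bin), `breaks`, `n_total_combinations`, `subsampled`.
#' @export
background_distribution <- function(snp_matrices, gene_matrices,
                                    mode = c("gene", "promoter_max"),
                                    budget = 1e5L, subsample = FALSE, seed = 1L,
                                    breaks = seq(-1, 1, by = 0.05)) {
  mode <- match.arg(mode)
  combos <- expand.grid(snp_id = names(snp_matrices), gene_id = names(gene_matrices),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_total <- nrow(combos)
  subsampled <- FALSE
  if (n_total > budget) {
    if (!subsample) {
      stop(sprintf("%d combinations exceed the budget of %d; set subsample = TRUE",
                   n_total, budget))
    }
    set.seed(seed)
    combos <- combos[sample.int(n_total, budget), , drop = FALSE]
    subsampled <- TRUE
  }
  vals <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sm <- snp_matrices[[combos$snp_id[i]]]
    if (mode == "gene") {
      vals[i] <- sparse_correlation(sm, gene_matrices[[combos$gene_id[i]]])$value
    } else {
      vals[i] <- promoter_max_score(sm, gene_matrices[[combos$gene_id[i]]])$value
    }
  }
  defined <- vals[!is.na(vals)]
  list(
    scores = defined,
    n_undefined = sum(is.na(vals)),
    histogram = tabulate(
      findInterval(pmin(pmax(defined, -1), 1), breaks,
                   rightmost.closed = TRUE, all.inside = TRUE),
      nbins = length(breaks) - 1L
    ),
    breaks = breaks,
    n_total_combinations = n_total,
    subsampled = subsampled
  )
}
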