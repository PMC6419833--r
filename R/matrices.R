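#' Extract reference-anchored subalignments in a single pass
#'
#' Walks the ordered MAF blocks once, slicing out the alignment columns
#' whose reference position falls inside each query interval. Columns
#' where the reference carries a gap are excluded, so every
#' subalignment has exactly `interval length` columns in reference
#' bases. A species missing from the block covering a column (or
#' outside any block) is absent at that column; its character is `NA`.
#' The block list is consumed exactly once however many (possibly
#' overlapping) intervals are requested.
#'
#' @param blocks Ordered list of [msa_block()]s (as from [read_maf()]),
#'   sorted by reference coordinate.
#' @param intervals `genomic_intervals` sorted by (chrom, start).
#' @param panel Character vector fixing the species order shared by all
#'   resulting matrices; defaults to the species seen across blocks
#'   (reference first, rest sorted).
#' @return List of subalignments, one per interval: each a list with
#'   `interval`, `panel`, and `chars` (panel x length character matrix,
#'   `NA` = absent, `"-"` = aligned gap).
#' @export
extract_subalignments <- function(blocks, intervals, panel = NULL) {
  n <- nrow(intervals)
  if (n > 1L) {
    o <- order(intervals$chrom, intervals$start)
    if (any(o != seq_len(n))) stop("intervals must be sorted by (chrom, start)")
  }
  if (is.null(panel)) {
    species <- unique(unlist(lapply(blocks, function(b) names(b$rows))))
    if (length(blocks) > 0L) {
      ref <- attr(blocks, "reference")
      if (is.null(ref)) ref <- blocks[[1L]]$reference
      panel <- c(ref, sort(setdiff(species, ref)))
    } else {
      panel <- character()
    }
  }
  subs <- vector("list", n)
  for (i in seq_len(n)) {
    w <- intervals$end[i] - intervals$start[i]
    if (w < 1L) stop("empty interval")
    subs[[i]] <- list(
      interval = intervals[i, , drop = FALSE],
      panel = panel,
      chars = matrix(NA_character_, nrow = length(panel), ncol = w,
                     dimnames = list(panel, NULL))
    )
  }
  if (n == 0L) return(subs)
  # active window of intervals possibly overlapping the current block
  first_open <- 1L
  touched <- logical(n)
  for (b in blocks) {
    bchrom <- b$reference_interval$chrom
    bstart <- b$reference_interval$start
    bend <- b$reference_interval$end
    ref_chars <- strsplit(b$rows[[1L]], "", fixed = TRUE)[[1L]]
    ref_cols <- which(ref_chars != "-")
    # advance past intervals that end before this block
    while (first_open <= n &&
           (intervals$chrom[first_open] < bchrom ||
            (intervals$chrom[first_open] == bchrom && intervals$end[first_open] <= bstart))) {
      first_open <- first_open + 1L
    }
    if (first_open > n) break
    block_split <- NULL  # lazily split rows only for blocks that matter
    j <- first_open
    while (j <= n && intervals$chrom[j] == bchrom && intervals$start[j] < bend) {
      s <- max(intervals$start[j], bstart)
      e <- min(intervals$end[j], bend)
      if (s < e) {
        if (is.null(block_split)) {
          block_split <- lapply(b$rows, function(r) strsplit(r, "", fixed = TRUE)[[1L]])
        }
        cols <- ref_cols[(s - bstart + 1L):(e - bstart)]
        dest <- (s - intervals$start[j] + 1L):(e - intervals$start[j])
        for (sp in names(block_split)) {
          if (sp %in% panel) {
            subs[[j]]$chars[sp, dest] <- block_split[[sp]][cols]
          }
        }
        touched[j] <- TRUE
      }
      j <- j + 1L
    }
  }
  if (any(!touched)) {
    warning(sprintf("%d interval(s) fall outside the alignment extent; returned all-absent",
                    sum(!touched)))
  }
  subs
}

.base_codes <- function(chars) {
  # A/C/G/T (case-insensitive) -> 1..4; gaps, ambiguity codes and absent -> 0.
  # Ambiguity codes (N etc.) never match anything, including themselves.
  code <- match(toupper(chars), c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  matrix(code, nrow = nrow(chars), dimnames = dimnames(chars))
}

#' Pairwise match rate of two species over a subalignment
#'
#' The fraction of the interval's reference columns where both species
#' are present, ungapped, and carry the identical nucleotide
#' (case-insensitive; ambiguity codes never match). The denominator is
#' the full interval length, so absence or gaps at a column count as
#' mismatches — a species with a missing alignment scores 0 against
#' everything.
#'
#' @param subalignment A subalignment from [extract_subalignments()].
#' @param species_a,species_b Species identifiers from the panel.
#' @return Match rate in \[0, 1\].
#' @export
pairwise_similarity <- function(subalignment, species_a, species_b) {
  panel <- subalignment$panel
  if (!(species_a %in% panel) || !(species_b %in% panel)) {
    stop("unknown species: ", paste(setdiff(c(species_a, species_b), panel), collapse = ", "))
  }
  code <- .base_codes(subalignment$chars)
  a <- code[species_a, ]
  b <- code[species_b, ]
  sum(a > 0L & a == b) / ncol(code)
}

#' Species-by-species similarity matrix of one genomic interval
#'
#' Scores all unordered species pairs by their match rate
#' ([pairwise_similarity()]); the diagonal holds each species' presence
#' fraction (share of interval columns where it is aligned and
#' ungapped), so a species absent from the whole interval has an
#' all-zero row and column. O(l^2 * interval length) for l species.
#'
#' @param subalignment A subalignment from [extract_subalignments()].
#' @return An l x l symmetric numeric matrix with values in \[0, 1\]
#'   and the panel as dimnames.
#' @export
build_similarity_matrix <- function(subalignment) {
  w <- ncol(subalignment$chars)
  if (is.null(w) || w < 1L) stop("empty interval")
  panel <- subalignment$panel
  l <- length(panel)
  code <- .base_codes(subalignment$chars)
  present <- !is.na(subalignment$chars) & subalignment$chars != "-"
  m <- matrix(0, l, l, dimnames = list(panel, panel))
  diag(m) <- rowSums(present) / w
  if (l >= 2L) {
    for (i in seq_len(l - 1L)) {
      ai <- code[i, ]
      for (j in (i + 1L):l) {
        bj <- code[j, ]
        v <- sum(ai > 0L & ai == bj) / w
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}

#' Similarity matrices for a set of loci in one pass
#'
#' Convenience wrapper: expands width-1 loci by `flank` bases on each
#' side (clipped at 0), extracts all subalignments in a single pass
#' through the MAF blocks, and builds one similarity matrix per locus.
#'
#' @inheritParams extract_subalignments
#' @param loci `genomic_intervals` (typically width-1 SNP or TSS loci),
#'   sorted; names become the matrix names.
#' @param flank Bases added on each side of each locus (interval size
#'   is a tunable, not a constant).
#' @return Named list of similarity matrices.
#' @export
locus_similarity_matrices <- function(blocks, loci, flank = 100L, panel = NULL) {
  windows <- genomic_intervals(
    loci$chrom, pmax(loci$start - flank, 0L), loci$end + flank,
    strand = loci$strand, name = loci$name
  )
  subs <- extract_subalignments(blocks, windows, panel = panel)
  mats <- lapply(subs, build_similarity_matrix)
  names(mats) <- loci$name
  mats
}
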