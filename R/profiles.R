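#' Extract a per-base conservation profile around a locus
#'
#' Takes the track scores at the locus and its `flank` bases up- and
#' downstream (2001 values for the default flank of 1000). Profiles are
#' ordered 5'-to-3' in transcriptional orientation: for a minus-strand
#' locus (e.g. a TSS of a reverse-strand gene) the window is reversed,
#' so "upstream" always means upstream of transcription. SNPs carry no
#' strand and use reference orientation. Positions off the covered
#' track (or off the chromosome) are `NA` (missing), which is distinct
#' from a neutral score of 0.
#'
#' @param track A [conservation_track()].
#' @param locus A single-row `genomic_intervals` of width 1.
#' @param flank Bases on each side (default 1000).
#' @return Numeric vector of length `2*flank + 1` with class
#'   `conservation_profile`; attribute `locus` keeps the anchor.
#' @export
extract_profile <- function(track, locus, flank = 1000L) {
  if (nrow(locus) != 1L) stop("extract_profile takes exactly one locus; see extract_profiles")
  if (interval_width(locus) != 1L) stop("profile locus must have width 1")
  pos <- (locus$start - flank):(locus$start + flank)
  scores <- rep(NA_real_, length(pos))
  ok <- pos >= 0L
  scores[ok] <- track_values(track, locus$chrom, pos[ok])
  if (identical(locus$strand, "-")) scores <- rev(scores)
  structure(scores, class = "conservation_profile", locus = locus, flank = flank)
}

#' Extract profiles for many loci
#'
#' @inheritParams extract_profile
#' @param loci A `genomic_intervals` data.frame of width-1 loci.
#' @return Matrix with one row per locus (rownames from `name` when
#'   available) and `2*flank + 1` columns.
#' @export
extract_profiles <- function(track, loci, flank = 1000L) {
  out <- matrix(NA_real_, nrow = nrow(loci), ncol = 2L * flank + 1L)
  for (i in seq_len(nrow(loci))) {
    out[i, ] <- as.numeric(extract_profile(track, loci[i, , drop = FALSE], flank))
  }
  if (!all(is.na(loci$name))) rownames(out) <- loci$name
  out
}

#' Logarithmic bin layout for a 2001-base profile
#'
#' The centre base sits in a bin of its own; moving outward the bins
#' double in size (2, 4, ..., 256) and the outermost bin on each side
#' absorbs the remaining 490 bases, reducing 2001 values to 19.
#'
#' @return Integer vector of the 19 bin sizes (sums to 2001).
#' @export
profile_bin_sizes <- function() {
  half <- c(490L, 256L, 128L, 64L, 32L, 16L, 8L, 4L, 2L)
  c(half, 1L, rev(half))
}

#' Reduce a profile by logarithmic binning
#'
#' Averages the 2001 per-base scores within the fixed logarithmic bin
#' layout ([profile_bin_sizes()]), weighting nearby bases more heavily
#' in the reduced representation. Missing bases are excluded from their
#' bin's mean; a bin with no observed base is `NA`.
#'
#' @param profile A [extract_profile()] result (or any numeric vector
#'   of length 2001).
#' @return A list of class `binned_profile`: `values` (19 bin means)
#'   and `bin_sizes`.
#' @export
bin_profile <- function(profile) {
  x <- as.numeric(profile)
  sizes <- profile_bin_sizes()
  if (length(x) != sum(sizes)) {
    stop(sprintf("bin_profile expects a %d-base profile, got %d", sum(sizes), length(x)))
  }
  idx <- rep.int(seq_along(sizes), sizes)
  sums <- tapply(x, idx, function(v) mean(v, na.rm = TRUE))
  values <- as.numeric(sums)
  values[is.nan(values)] <- NA_real_
  structure(list(values = values, bin_sizes = sizes), class = "binned_profile")
}

#' Bin many profiles
#'
#' @param profiles Matrix of profiles (rows = loci, 2001 columns).
#' @return Matrix with 19 columns of bin means.
#' @export
bin_profiles <- function(profiles) {
  t(apply(profiles, 1L, function(p) bin_profile(p)$values))
}

#' Average pileup of conservation profiles
#'
#' Per-position mean over a set of profiles, skipping missing bases:
#' the average conservation landscape around a class of loci. Use
#' `zoom` to restrict to the central `+/- zoom` bases.
#'
#' @param profiles Matrix of profiles (rows = loci).
#' @param zoom Optional half-width; e.g. `zoom = 100` returns the
#'   central 201 positions.
#' @return Numeric vector of per-position means.
#' @export
average_pileup <- function(profiles, zoom = NULL) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  if (nrow(profiles) < 1L) stop("average_pileup needs at least one profile")
  m <- colMeans(profiles, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  if (!is.null(zoom)) {
    centre <- (length(m) + 1L) %/% 2L
    m <- m[(centre - zoom):(centre + zoom)]
  }
  m
}
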