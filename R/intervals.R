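#' Construct a set of genomic intervals
#'
#' All coordinates in this package are 0-based half-open (BED-style):
#' `start` is the first base covered, `end` is one past the last.
#' Conversion to and from 1-based file formats (e.g. WIG fixedStep)
#' happens only inside the readers and writers.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, 0-based exclusive ends.
#' @param strand Strand per interval: `"+"`, `"-"`, or `"*"` (unstranded).
#' @param name Optional identifier per interval.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name` and class `genomic_intervals`.
#' @examples
#' genomic_intervals("chr1", 99, 100, "+", "rs1")
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", name = NA_character_) {
  n <- max(length(chrom), length(start))
  chrom <- rep_len(as.character(chrom), n)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  name <- rep_len(as.character(name), n)
  if (length(start) != n || length(end) != n) {
    stop("start and end must have equal length")
  }
  if (any(is.na(start)) || any(is.na(end))) stop("start/end must not be NA")
  if (any(start < 0L)) stop("negative start coordinate")
  if (any(start >= end)) stop("interval start must be < end (0-based half-open)")
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be one of '+', '-', '*'")
  out <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    strand = strand, name = name, stringsAsFactors = FALSE
  )
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Interval widths
#' @param x A `genomic_intervals` data.frame.
#' @return Integer vector of lengths (`end - start`).
#' @export
interval_width <- function(x) x$end - x$start
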