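#' Read BED3/BED6 intervals
#'
#' BED is already 0-based half-open, matching the internal convention.
#' Strand is taken from column 6 when present, otherwise intervals are
#' unstranded (`"*"`); the name from column 4 when present.
#'
#' @param path Path to BED text.
#' @return A [genomic_intervals()] data.frame.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  nc <- ncol(tab)
  if (nc < 3L) stop("BED format error: fewer than 3 columns")
  strand <- if (nc >= 6L) ifelse(tab[[6L]] == ".", "*", tab[[6L]]) else "*"
  name <- if (nc >= 4L) as.character(tab[[4L]]) else NA_character_
  genomic_intervals(tab[[1L]], tab[[2L]], tab[[3L]], strand = strand, name = name)
}

#' Write intervals as BED6
#'
#' @param x A `genomic_intervals` data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- ifelse(is.na(x$name), ".", x$name)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end, name,
                   ifelse(x$strand == "*", ".", x$strand))
  writeLines(lines, path)
  invisible(path)
}
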