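#' Build a conservation track from per-chromosome runs
#'
#' A track stores real-valued per-base scores (PhyloP convention:
#' positive = conserved, negative = accelerated, 0 = neutral rate).
#' Positions not covered by any run are *missing* and are reported as
#' `NA` — distinct from a score of 0, which is a meaningful neutral
#' value.
#'
#' @param runs List of runs, each `list(chrom=, start=, values=)` with
#'   `start` 0-based.
#' @return An object of class `conservation_track`.
#' @export
conservation_track <- function(runs) {
  for (r in runs) {
    if (any(!is.finite(r$values))) stop("conservation scores must be finite")
    if (r$start < 0L) stop("negative run start")
  }
  chroms <- unique(vapply(runs, function(r) r$chrom, character(1)))
  per_chrom <- list()
  for (ch in chroms) {
    rs <- Filter(function(r) r$chrom == ch, runs)
    starts <- vapply(rs, function(r) as.integer(r$start), integer(1))
    ends <- starts + vapply(rs, function(r) length(r$values), integer(1))
    ord <- order(starts)
    rs <- rs[ord]; starts <- starts[ord]; ends <- ends[ord]
    if (length(rs) > 1L && any(starts[-1L] < ends[-length(ends)])) {
      stop(sprintf("overlapping fixedStep declarations on %s", ch))
    }
    offset <- starts[1L]
    len <- max(ends) - offset
    values <- rep(NA_real_, len)
    for (k in seq_along(rs)) {
      values[(starts[k] - offset + 1L):(ends[k] - offset)] <- rs[[k]]$values
    }
    per_chrom[[ch]] <- list(offset = offset, values = values)
  }
  structure(list(chroms = per_chrom), class = "conservation_track")
}

#' Query per-base track values
#'
#' @param track A `conservation_track`.
#' @param chrom Chromosome name.
#' @param positions Integer vector of 0-based positions.
#' @return Numeric vector of scores; `NA` for positions not covered by
#'   the track (missing, as opposed to neutral 0).
#' @export
track_values <- function(track, chrom, positions) {
  ch <- track$chroms[[chrom]]
  if (is.null(ch)) return(rep(NA_real_, length(positions)))
  idx <- positions - ch$offset + 1L
  out <- rep(NA_real_, length(positions))
  ok <- idx >= 1L & idx <= length(ch$values)
  out[ok] <- ch$values[idx[ok]]
  out
}

#' Read a fixedStep WIG conservation track
#'
#' Only the `fixedStep` dialect with `step=1` (and `span=1`) is
#' supported; the UCSC per-base conservation tracks use this layout.
#' WIG `start` is 1-based and converted to the package's 0-based
#' convention on read.
#'
#' @param path Path to WIG text.
#' @return A [conservation_track()].
#' @export
read_fixedstep_wig <- function(path) {
  lines <- trimws(readLines(path))
  keep <- nzchar(lines) & !grepl("^#", lines) & !grepl("^track", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (any(grepl("^variableStep", lines))) {
    stop(sprintf("unsupported WIG dialect at line %d: variableStep",
                 lineno[grep("^variableStep", lines)[1L]]))
  }
  is_decl <- grepl("^fixedStep", lines)
  if (length(lines) > 0L && !is_decl[1L]) {
    stop(sprintf("WIG format error at line %d: value outside a fixedStep run", lineno[1L]))
  }
  decl_idx <- which(is_decl)
  runs <- vector("list", length(decl_idx))
  for (k in seq_along(decl_idx)) {
    i <- decl_idx[k]
    kv <- strsplit(strsplit(lines[i], "\\s+")[[1L]][-1L], "=")
    decl <- stats::setNames(
      as.list(vapply(kv, `[`, character(1), 2L)),
      vapply(kv, `[`, character(1), 1L)
    )
    if (is.null(decl$chrom) || is.null(decl$start)) {
      stop(sprintf("WIG format error at line %d: fixedStep needs chrom= and start=", lineno[i]))
    }
    step <- if (is.null(decl$step)) 1L else as.integer(decl$step)
    span <- if (is.null(decl$span)) 1L else as.integer(decl$span)
    if (step != 1L || span != 1L) {
      stop(sprintf("unsupported WIG dialect at line %d: only fixedStep step=1 span=1 is supported",
                   lineno[i]))
    }
    last <- if (k < length(decl_idx)) decl_idx[k + 1L] - 1L else length(lines)
    if (last < i + 1L) stop(sprintf("fixedStep declaration at line %d has no values", lineno[i]))
    vals <- as.numeric(lines[(i + 1L):last])
    # WIG start is 1-based; internal coordinates are 0-based
    runs[[k]] <- list(chrom = decl$chrom, start = as.integer(decl$start) - 1L, values = vals)
  }
  conservation_track(runs)
}

#' Write a conservation track as fixedStep WIG
#'
#' Contiguous covered stretches are emitted as separate fixedStep runs;
#' missing positions are simply not written. 0-based internal starts
#' are converted back to WIG's 1-based convention.
#'
#' @param track A `conservation_track`.
#' @param path Output path.
#' @export
write_fixedstep_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$chroms)) {
    ch <- track$chroms[[chrom]]
    covered <- !is.na(ch$values)
    r <- rle(covered)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      i0 <- pos[k]; i1 <- pos[k + 1L] - 1L
      start0 <- ch$offset + i0 - 1L
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1", chrom, start0 + 1L), con)
      writeLines(format(ch$values[i0:i1], trim = TRUE, digits = 15), con)
    }
  }
  invisible(path)
}
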