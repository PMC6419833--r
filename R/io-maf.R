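#' Construct an MSA block
#'
#' One alignment block of a whole-genome multiple sequence alignment,
#' anchored on a reference genome. Species identifiers are the genome
#' names (the part of a MAF `src` field before the first dot).
#'
#' @param chrom Reference chromosome.
#' @param start 0-based start of the block on the reference.
#' @param rows Named character vector of aligned sequences (may contain
#'   `-` gaps); the first element must be the reference species and its
#'   non-gap character count defines the reference extent.
#' @return A list with class `msa_block`: `reference_interval`
#'   (`genomic_intervals` row), `reference` (species name), `rows`,
#'   `column_count`.
#' @export
msa_block <- function(chrom, start, rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("rows must be a named character vector (names are species)")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("all rows of an MSA block must have equal length")
  }
  ref <- names(rows)[1L]
  ref_len <- nchar(gsub("-", "", rows[[1L]], fixed = TRUE))
  if (ref_len == 0L) stop("reference row is all gaps")
  out <- list(
    reference_interval = genomic_intervals(chrom, start, start + ref_len),
    reference = ref,
    rows = rows,
    column_count = unname(widths[1L])
  )
  class(out) <- "msa_block"
  out
}

#' Read a MAF (multiple alignment format) file
#'
#' Blocks must be sorted by reference start coordinate. The reference
#' species of each block is the species of its first `s` line and must
#' agree across blocks (UCSC multiz layout). Species sets may differ per
#' block. Only `s` lines are interpreted; `i`/`e`/`q` lines are skipped.
#'
#' @param path Path to a MAF text file.
#' @return List of [msa_block()] objects in file order, with attribute
#'   `reference` (reference species name).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL        # list(species=..., seqs=..., lineno=...)
  cur_meta <- NULL   # reference chrom/start for the current block
  flush_block <- function() {
    if (is.null(cur)) return(NULL)
    widths <- nchar(cur$seqs)
    if (length(unique(widths)) != 1L) {
      bad <- which(widths != widths[1L])[1L]
      stop(sprintf(
        "MAF format error at line %d: row length %d differs from first row length %d",
        cur$lineno[bad], widths[bad], widths[1L]
      ))
    }
    rows <- cur$seqs
    names(rows) <- cur$species
    msa_block(cur_meta$chrom, cur_meta$start, rows)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^#", line) || grepl("^\\s*$", line)) {
      if (grepl("^\\s*$", line) && !is.null(cur)) {
        blocks[[length(blocks) + 1L]] <- flush_block()
        cur <- NULL
      }
      next
    }
    fields <- strsplit(trimws(line), "\\s+")[[1L]]
    tag <- fields[[1L]]
    if (tag == "a") {
      if (!is.null(cur)) {
        blocks[[length(blocks) + 1L]] <- flush_block()
      }
      cur <- list(species = character(), seqs = character(), lineno = integer())
      cur_meta <- NULL
    } else if (tag == "s") {
      if (is.null(cur)) stop(sprintf("MAF format error at line %d: 's' line outside a block", i))
      if (length(fields) < 7L) stop(sprintf("MAF format error at line %d: truncated 's' line", i))
      src <- fields[[2L]]
      species <- sub("\\..*$", "", src)
      if (length(cur$species) == 0L) {
        chrom <- sub("^[^.]*\\.", "", src)
        if (identical(chrom, src)) chrom <- src  # no dot: src is the chrom
        strand <- fields[[5L]]
        if (strand != "+") {
          stop(sprintf("MAF error at line %d: reference row must be on '+' strand", i))
        }
        cur_meta <- list(chrom = chrom, start = as.integer(fields[[3L]]))
      }
      cur$species <- c(cur$species, species)
      cur$seqs <- c(cur$seqs, fields[[7L]])
      cur$lineno <- c(cur$lineno, i)
    }
    # i/e/q lines ignored
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- flush_block()
  if (length(blocks) == 0L) return(structure(list(), reference = NA_character_))
  refs <- vapply(blocks, function(b) b$reference, character(1))
  if (length(unique(refs)) != 1L) {
    stop("MAF error: blocks disagree on reference species: ", paste(unique(refs), collapse = ", "))
  }
  starts <- vapply(blocks, function(b) b$reference_interval$start, integer(1))
  chroms <- vapply(blocks, function(b) b$reference_interval$chrom, character(1))
  ord <- order(chroms, starts)
  if (any(ord != seq_along(blocks))) {
    bad <- which(ord != seq_along(blocks))[1L]
    stop(sprintf("MAF ordering error: block %d is not sorted by reference coordinate", bad))
  }
  structure(blocks, reference = refs[1L])
}

#' Write MSA blocks as MAF
#'
#' @param blocks List of [msa_block()] objects.
#' @param path Output path.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  writeLines("", con)
  for (b in blocks) {
    writeLines("a", con)
    sp <- names(b$rows)
    for (j in seq_along(sp)) {
      seq_j <- b$rows[[j]]
      size_j <- nchar(gsub("-", "", seq_j, fixed = TRUE))
      if (j == 1L) {
        src <- paste0(sp[j], ".", b$reference_interval$chrom)
        start_j <- b$reference_interval$start
      } else {
        src <- paste0(sp[j], ".chr")
        start_j <- 0L
      }
      writeLines(sprintf("s %s %d %d + %d %s", src, start_j, size_j, size_j, seq_j), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
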