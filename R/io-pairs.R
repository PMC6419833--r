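#' Read a SNP-gene hypothesis catalog (TSV)
#'
#' The catalog lists cis-eQTL association tests: one SNP-gene pair per
#' row with its nominal p-value and, optionally, a coevolution score.
#' Pair distance is computed as `|snp_pos - tss_pos|` for
#' same-chromosome pairs and is `NA` for inter-chromosomal pairs.
#'
#' @param path TSV with header columns `snp_id`, `gene_id`, `snp_chrom`,
#'   `snp_pos`, `gene_chrom`, `tss_pos`, `nominal_p` and optionally
#'   `score`.
#' @return A data.frame (class `hypothesis_catalog`) with the input
#'   columns plus `distance`.
#' @export
read_pairs_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("snp_id", "gene_id", "snp_chrom", "snp_pos", "gene_chrom",
                "tss_pos", "nominal_p")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("pairs table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  hypothesis_catalog(tab)
}

#' Construct / validate a hypothesis catalog
#'
#' @param tab A data.frame with at least `snp_id`, `gene_id`,
#'   `nominal_p`; positional columns (`snp_chrom`, `snp_pos`,
#'   `gene_chrom`, `tss_pos`) are used to (re)compute `distance`.
#' @return The validated data.frame with class `hypothesis_catalog`.
#' @export
hypothesis_catalog <- function(tab) {
  if (nrow(tab) > 0L) {
    if (any(is.na(tab$nominal_p)) || any(tab$nominal_p < 0) || any(tab$nominal_p > 1)) {
      stop("nominal_p values must lie in [0, 1]")
    }
  }
  if (all(c("snp_chrom", "snp_pos", "gene_chrom", "tss_pos") %in% names(tab))) {
    tab$distance <- ifelse(tab$snp_chrom == tab$gene_chrom,
                           abs(tab$snp_pos - tab$tss_pos), NA_integer_)
  }
  class(tab) <- c("hypothesis_catalog", "data.frame")
  tab
}

#' Write a hypothesis catalog as TSV
#' @param catalog A `hypothesis_catalog` data.frame.
#' @param path Output path.
#' @export
write_pairs_table <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
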