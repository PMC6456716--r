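#' Read pipeline input tables
#'
#' Readers for the plain-text input formats: RPKM tables (first column row
#' id, header of condition ids), the site annotation table (BED6-compatible
#' columns plus `site_id`, `host_gene`, `support_count`; 0-based half-open
#' coordinates), the two-column replicate map, and the disease-MeSH term
#' table (one term per row).
#'
#' @param path File path (TSV with header).
#' @return A tibble.
#' @rdname input-io
#' @export
read_rpkm_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("RPKM table needs an id column plus value columns")
  vals <- as.matrix(df[, -1])
  if (!is.numeric(vals) || anyNA(vals)) abort("RPKM values must be numeric and complete")
  if (any(vals < 0)) abort("RPKM values must be >= 0")
  if (anyDuplicated(df[[1]])) abort("duplicate row ids in RPKM table")
  df
}

#' @rdname input-io
#' @export
read_site_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_site_table(df)
}

#' @rdname input-io
#' @export
read_replicate_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("replicate map needs two columns")
  names(df)[1:2] <- c("condition_id", "group")
  df
}

#' @rdname input-io
#' @export
read_disease_terms <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("disease-term table needs two columns")
  names(df)[1:2] <- c("disease", "term")
  df
}
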