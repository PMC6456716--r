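#' Methylation level (M-value) from paired IP / Input RPKM
#'
#' Quantifies the methylation level of an m6A site as the log2 ratio of read
#' abundance in the immunoprecipitated (IP) library over the Input control,
#' with a fixed pseudo-count of 0.1 on both terms so the value is always
#' finite: `log2((rpkm_ip + 0.1) / (rpkm_input + 0.1))`.
#'
#' @param rpkm_ip,rpkm_input Non-negative numeric vectors of RPKM values
#'   (recycled to a common length).
#' @return Numeric vector of M-values.
#' @examples
#' m_value(1.9, 0.9)  # 1
#' m_value(0, 0.9)    # log2(0.1 / 1.0)
#' @export
m_value <- function(rpkm_ip, rpkm_input) {
  if (!is.numeric(rpkm_ip) || !is.numeric(rpkm_input)) {
    abort("RPKM inputs must be numeric")
  }
  if (anyNA(rpkm_ip) || anyNA(rpkm_input)) abort("RPKM inputs must not contain NA")
  if (any(rpkm_ip < 0) || any(rpkm_input < 0)) abort("RPKM values must be >= 0")
  log2((rpkm_ip + 0.1) / (rpkm_input + 0.1))
}

#' Merge replicate columns of an RPKM table
#'
#' Collapses biological replicates of the same experimental condition into a
#' single column by taking the arithmetic mean of their RPKM values. Output
#' columns follow the order in which each condition first appears in the
#' input.
#'
#' @param data Data frame whose first column holds row ids (site or gene
#'   ids) and remaining columns hold per-replicate RPKM values; or a numeric
#'   matrix with rownames.
#' @param replicate_map Data frame with two columns mapping replicate column
#'   name to experimental-condition label (`condition_id`, `group`).
#' @param fun Summary applied within a replicate group; defaults to `mean`.
#' @return Tibble with the id column and one column per condition.
#' @export
merge_replicates <- function(data, replicate_map, fun = mean) {
  m <- as_id_matrix(data, "data")
  if (!is.data.frame(replicate_map) || ncol(replicate_map) < 2) {
    abort("`replicate_map` must be a two-column data frame (condition_id, group)")
  }
  cond <- as.character(replicate_map[[1]])
  grp <- as.character(replicate_map[[2]])
  if (anyDuplicated(cond)) abort("each replicate column may belong to only one group")
  missing_cols <- setdiff(colnames(m), cond)
  if (length(missing_cols)) {
    abort(paste0("columns without a replicate group: ", paste(missing_cols, collapse = ", ")))
  }
  groups_in_order <- unique(grp[match(colnames(m), cond)])
  merged <- vapply(groups_in_order, function(g) {
    cols <- colnames(m)[colnames(m) %in% cond[grp == g]]
    if (!length(cols)) abort(paste0("empty replicate group: ", g))
    apply(m[, cols, drop = FALSE], 1, fun)
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) merged <- matrix(merged, nrow = 1, dimnames = list(rownames(m), groups_in_order))
  out <- as_tibble(merged)
  out <- dplyr::bind_cols(tibble(id = rownames(m)), out)
  names(out)[1] <- names(as_tibble(as.data.frame(data))[1]) %||% "id"
  if (is.matrix(data)) names(out)[1] <- "id"
  out
}

#' Quantile-normalize a values matrix
#'
#' Forces every column to share the identical value multiset (the row-wise
#' mean of per-rank values across columns) while preserving within-column
#' ranks. Ties receive the mean of the tied ranks' reference values.
#'
#' @param data Numeric matrix, or data frame whose first column holds row
#'   ids.
#' @return Object of the same shape as the input with normalized values.
#' @export
quantile_normalize <- function(data) {
  is_df <- is.data.frame(data)
  m <- if (is_df) as_id_matrix(data, "data") else data
  stop_if_not_numeric_matrix(m, "data")
  if (nrow(m) < 1 || ncol(m) < 2) abort("need >= 1 row and >= 2 columns to quantile-normalize")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (is_df) {
    out <- dplyr::bind_cols(data[1], as_tibble(qn))
    return(out)
  }
  qn
}

new_profile <- function(ids, conditions, values, kind, sites = NULL) {
  stopifnot(is.matrix(values))
  if (!all(is.finite(values))) abort("profile values must be finite")
  if (nrow(values) != length(ids) || ncol(values) != length(conditions)) {
    abort("profile matrix dimensions do not match ids x conditions")
  }
  dimnames(values) <- list(ids, conditions)
  structure(
    list(ids = ids, conditions = conditions, values = values, sites = sites),
    class = c(paste0(kind, "_profile"), "mw_profile")
  )
}

validate_site_table <- function(sites) {
  sites <- as_tibble(sites)
  needed <- c("site_id", "chrom", "start", "end", "strand", "host_gene", "support_count")
  miss <- setdiff(needed, names(sites))
  if (length(miss)) abort(paste0("site table missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(sites$site_id)) abort("site_id values must be unique")
  if (!all(sites$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (!all(sites$start < sites$end)) abort("site intervals must satisfy start < end")
  if (!all(sites$support_count >= 0)) abort("support_count must be >= 0")
  sites
}

#' Build a methylation profile from IP / Input RPKM tables
#'
#' Merges replicates (arithmetic mean), computes M-values per merged
#' condition, and quantile-normalizes. The default order computes M-values
#' first and normalizes the M-value matrix; `normalize = "rpkm_first"`
#' quantile-normalizes the IP and Input RPKM matrices before forming
#' M-values.
#'
#' @param ip,input Data frames (first column `site_id`) or matrices of
#'   non-negative RPKM values with identical row ids and columns.
#' @param sites Site annotation table with columns `site_id`, `chrom`,
#'   `start`, `end`, `strand`, `host_gene`, `support_count`.
#' @param replicate_map Optional replicate-to-condition map passed to
#'   [merge_replicates()]; `NULL` means columns are already one per
#'   condition.
#' @param normalize `"m_first"` (default) or `"rpkm_first"`, see above;
#'   `"none"` skips quantile normalization.
#' @return A `meth_profile` object: site metadata plus a sites x conditions
#'   M-value matrix.
#' @export
build_methylation_profile <- function(ip, input, sites,
                                      replicate_map = NULL,
                                      normalize = c("m_first", "rpkm_first", "none")) {
  normalize <- match.arg(normalize)
  sites <- validate_site_table(sites)
  if (!is.null(replicate_map)) {
    ip <- merge_replicates(ip, replicate_map)
    input <- merge_replicates(input, replicate_map)
  }
  mi <- as_id_matrix(ip, "ip")
  mn <- as_id_matrix(input, "input")
  if (!identical(dim(mi), dim(mn)) || !identical(rownames(mi), rownames(mn)) ||
      !identical(colnames(mi), colnames(mn))) {
    abort("ip and input tables must share row ids and condition columns")
  }
  ord <- match(sites$site_id, rownames(mi))
  if (anyNA(ord)) abort("every site in `sites` needs a row in the RPKM tables")
  mi <- mi[ord, , drop = FALSE]
  mn <- mn[ord, , drop = FALSE]
  if (normalize == "rpkm_first" && ncol(mi) >= 2) {
    mi <- quantile_normalize(mi)
    mn <- quantile_normalize(mn)
  }
  m <- matrix(m_value(mi, mn), nrow = nrow(mi), dimnames = dimnames(mi))
  if (normalize == "m_first" && ncol(m) >= 2) m <- quantile_normalize(m)
  new_profile(sites$site_id, colnames(m), m, "meth", sites = sites)
}

#' Build a gene expression profile from an RPKM table
#'
#' Expression is taken from the Input control libraries of MeRIP-seq data;
#' replicates are merged by arithmetic mean and values quantile-normalized.
#'
#' @param rpkm Data frame (first column gene id) or matrix of non-negative
#'   RPKM values.
#' @param replicate_map Optional replicate map, see [merge_replicates()].
#' @param normalize Quantile-normalize after merging (default `TRUE`).
#' @return An `expr_profile` object.
#' @export
build_expression_profile <- function(rpkm, replicate_map = NULL, normalize = TRUE) {
  if (!is.null(replicate_map)) rpkm <- merge_replicates(rpkm, replicate_map)
  m <- as_id_matrix(rpkm, "rpkm")
  if (any(m < 0)) abort("RPKM values must be >= 0")
  if (normalize && ncol(m) >= 2) m <- quantile_normalize(m)
  new_profile(rownames(m), colnames(m), m, "expr")
}

#' Filter m6A sites on experimental support, level and variability
#'
#' Applies three filters in order, each percentile computed on the survivors
#' of the previous step: (a) keep sites supported by strictly more than
#' `min_support` experiments; (b) keep sites whose mean M-value lies at or
#' below the `level_pct`-th percentile of per-site means (the
#' `level_rule = "ge_pct"` alternative keeps the upper tail instead);
#' (c) keep sites whose M-value variance lies at or above the
#' `(100 - var_pct)`-th percentile of per-site variances, i.e. the top
#' `var_pct` percentiles by variability. Ties at a threshold are kept.
#'
#' @param profile A `meth_profile`.
#' @param min_support Strict lower bound on `support_count` (default 10).
#' @param level_pct Percentile bound on the mean methylation level
#'   (default 70).
#' @param var_pct Retained top-percentile span of variances (default 80).
#' @param level_rule `"le_pct"` (default: keep means at/below the
#'   percentile) or `"ge_pct"`.
#' @return A filtered `meth_profile`; attribute `"filter_counts"` records
#'   survivors after each step.
#' @export
filter_sites <- function(profile, min_support = 10, level_pct = 70, var_pct = 80,
                         level_rule = c("le_pct", "ge_pct")) {
  level_rule <- match.arg(level_rule)
  if (!inherits(profile, "meth_profile")) abort("`profile` must be a meth_profile")
  if (!nrow(profile$values)) abort("profile is empty")
  counts <- c(input = nrow(profile$values))

  keep <- profile$sites$support_count > min_support
  m <- profile$values[keep, , drop = FALSE]
  sites <- profile$sites[keep, , drop = FALSE]
  counts["support"] <- nrow(m)

  if (nrow(m)) {
    mu <- rowMeans(m)
    thr <- pctl(mu, level_pct)
    keep <- if (level_rule == "le_pct") mu <= thr else mu >= pctl(mu, 100 - level_pct)
    m <- m[keep, , drop = FALSE]
    sites <- sites[keep, , drop = FALSE]
  }
  counts["level"] <- nrow(m)

  if (nrow(m)) {
    v <- apply(m, 1, var)
    keep <- v >= pctl(v, 100 - var_pct)
    m <- m[keep, , drop = FALSE]
    sites <- sites[keep, , drop = FALSE]
  }
  counts["variance"] <- nrow(m)

  if (!nrow(m)) {
    abort(paste0(
      "all sites filtered out (input ", counts["input"],
      ", after support ", counts["support"],
      ", after level ", counts["level"],
      ", after variance ", counts["variance"], ")"
    ))
  }
  out <- new_profile(sites$site_id, profile$conditions, m, "meth", sites = sites)
  attr(out, "filter_counts") <- counts
  out
}

#' @export
print.mw_profile <- function(x, ...) {
  kind <- if (inherits(x, "meth_profile")) "methylation (M-value)" else "expression"
  cat("<", kind, " profile: ", length(x$ids), " rows x ",
      length(x$conditions), " conditions>\n", sep = "")
  invisible(x)
}

#' Tidy a profile into long format
#'
#' @param x A `meth_profile` or `expr_profile`.
#' @param ... Unused.
#' @return Tibble with columns `id`, `condition`, `value`.
#' @export
tidy.mw_profile <- function(x, ...) {
  tibble(
    id = rep(x$ids, times = length(x$conditions)),
    condition = rep(x$conditions, each = length(x$ids)),
    value = as.vector(x$values)
  )
}
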