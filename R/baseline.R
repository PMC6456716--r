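#' Hypergeometric upper-tail p-value for gene-set overlap
#'
#' Probability of observing at least `y` shared genes between a disease's
#' gene set (size `n`) and a site's gene set (size `x`) when `n` genes are
#' drawn without replacement from a universe of `m` genes of which `x` are
#' linked to the site:
#' `P(Y >= y) = 1 - sum_{i=0}^{y-1} C(x, i) C(m - x, n - i) / C(m, n)`.
#' Returns 1 when `y = 0`.
#'
#' @param m Total number of genes in the analysis.
#' @param n Number of genes linked to the disease.
#' @param x Number of genes linked to the m6A site.
#' @param y Number of genes linked to both.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeom_pvalue <- function(m, n, x, y) {
  vals <- c(m = m, n = n, x = x, y = y)
  if (any(vals != round(vals)) || any(vals < 0)) {
    abort("m, n, x, y must be non-negative integers")
  }
  if (n > m || x > m) abort("n and x must not exceed m")
  if (y > min(n, x)) abort("y must not exceed min(n, x)")
  if (y == 0) return(1)
  phyper(y - 1, m = x, n = m - x, k = n, lower.tail = FALSE)
}

#' Hypergeometric baseline ranking of m6A sites for a disease
#'
#' Scores every site by the significance of the overlap between the genes
#' linked to the disease (disease-gene network) and the genes linked to the
#' site (gene-site network), using only those two bipartite sub-networks.
#' Sites are ranked by ascending p-value with lexicographic tie-breaking.
#'
#' @param dg Disease-gene `assoc_net` (`from` = disease).
#' @param sg Site-gene `assoc_net` (`from` = site).
#' @param disease Disease id present in `dg`'s universe.
#' @param gene_universe Optional character vector defining the total gene
#'   count `m`; defaults to the union of the gene universes of `dg` and
#'   `sg`.
#' @return Tibble with columns `site_id`, `p_value`, `rank`.
#' @export
baseline_predict <- function(dg, sg, disease, gene_universe = NULL) {
  if (!(disease %in% attr(dg, "universe_a"))) {
    abort(paste0("disease not in the disease-gene network: ", disease))
  }
  genes <- unique(c(attr(dg, "universe_b"), attr(sg, "universe_b"),
                    gene_universe))
  m <- length(genes)
  d_genes <- unique(dg$to[dg$from == disease])
  sites <- attr(sg, "universe_a")
  site_genes <- split(sg$to, factor(sg$from, levels = sites))
  p <- vapply(sites, function(s) {
    gx <- unique(site_genes[[s]])
    hypergeom_pvalue(m, length(d_genes), length(gx),
                     length(intersect(gx, d_genes)))
  }, numeric(1))
  out <- tibble(site_id = sites, p_value = unname(p))
  out <- dplyr::arrange(out, .data$p_value, .data$site_id)
  out$rank <- seq_len(nrow(out))
  out
}
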