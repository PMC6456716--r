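#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot pooled ROC curves of a cross-validation run
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot with one curve per method, AUC in the legend.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- purrr::list_rbind(imap(object$roc, function(rr, m) {
    dplyr::mutate(tidy(rr),
                  method = sprintf("%s (AUC %.3f)", m, rr$auc))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot top-ranked nodes of a restart walk
#'
#' @param object An `rwr_result`.
#' @param n Number of site-layer nodes to show (default 20).
#' @param ... Unused.
#' @return A ggplot bar chart of stationary probabilities.
#' @export
autoplot.rwr_result <- function(object, n = 20, ...) {
  top <- head(rank_sites(object), n)
  top$site_id <- factor(top$site_id, levels = rev(top$site_id))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$probability, y = .data$site_id)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Stationary probability", y = NULL,
                  title = paste0("Top sites for seed ", object$seed_id)) +
    ggplot2::theme_minimal()
}

#' Plot the host-gene correlation diagnostic
#'
#' Sorted per-site correlation curves: each permutation null in grey, the
#' observed site / host-gene correlations in red. Overlapping curves mean
#' methylation levels are no more correlated with their host gene's
#' expression than with a random gene's.
#'
#' @param object A `host_gene_diag` from [host_gene_diagnostic()].
#' @param max_null Cap on the number of null curves drawn (default 200).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.host_gene_diag <- function(object, max_null = 200, ...) {
  n_sites <- nrow(object$self)
  frac <- seq_len(n_sites) / n_sites
  np <- ncol(object$null)
  shown <- seq_len(min(np, max_null))
  null_df <- purrr::list_rbind(lapply(shown, function(j) {
    tibble(perm = j, frac = frac, corr = sort(object$null[, j]))
  }))
  self_df <- tibble(frac = frac, corr = sort(object$self$corr))
  p <- ggplot2::ggplot()
  if (nrow(null_df)) {
    p <- p + ggplot2::geom_line(
      data = null_df,
      ggplot2::aes(x = .data$frac, y = .data$corr, group = .data$perm),
      colour = "grey70", alpha = 0.3, linewidth = 0.2
    )
  }
  p +
    ggplot2::geom_line(data = self_df,
                       ggplot2::aes(x = .data$frac, y = .data$corr),
                       colour = "#b2182b", linewidth = 0.8) +
    ggplot2::labs(x = "Fraction of sites (sorted)",
                  y = "Pearson correlation",
                  title = "Site methylation vs host-gene expression") +
    ggplot2::theme_minimal()
}
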