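#' Partition disease-gene associations into cross-validation folds
#'
#' Randomly assigns each association to one of `k` folds with sizes
#' differing by at most one; the partition is reproducible from
#' `rng_seed`.
#'
#' @param dg Disease-gene `assoc_net`.
#' @param k Number of folds (default 10).
#' @param rng_seed Integer seed.
#' @return A `cv_folds` tibble with columns `from`, `to`, `fold`.
#' @export
make_folds <- function(dg, k = 10, rng_seed) {
  if (k < 2) abort("k must be at least 2")
  n <- nrow(dg)
  if (n < k) abort("need at least k associations")
  set.seed(rng_seed)
  fold <- sample(rep_len(seq_len(k), n))
  structure(
    tibble(from = dg$from, to = dg$to, fold = fold),
    class = c("cv_folds", class(tibble())), k = k, rng_seed = rng_seed
  )
}

#' ROC curve and AUC with midrank tie handling
#'
#' Computes the trapezoidal area under the ROC curve; ties are handled by
#' midranks, making the AUC identical to the normalized Mann-Whitney
#' U statistic.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1); both classes must be
#'   present.
#' @return A `roc_result`: `fpr` / `tpr` vectors and the `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels must align")
  if (anyNA(scores) || anyNA(labels)) abort("scores and labels must not contain NA")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  rk <- rank(scores)
  auc <- (sum(rk[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  structure(
    list(fpr = c(0, fp / n0), tpr = c(0, tp / n1), auc = auc,
         n_pos = n1, n_neg = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result: AUC ", format(x$auc, digits = 4), " (", x$n_pos,
      " pos / ", x$n_neg, " neg)>\n", sep = "")
  invisible(x)
}

#' Tidy ROC curve points
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return Tibble with columns `fpr`, `tpr`.
#' @export
tidy.roc_result <- function(x, ...) tibble(fpr = x$fpr, tpr = x$tpr)

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Cross-validated evaluation of disease-gene recovery
#'
#' For each fold, removes the test-fold disease-gene edges, reassembles the
#' transition matrix on the training edges, and scores the held-out
#' disease-gene pairs as positives against genes never associated with the
#' disease as negatives (`negatives = "all_genes"` instead uses every
#' non-positive gene). Scores are pooled across folds for the overall ROC;
#' per-disease AUCs cover diseases with at least one positive and one
#' negative scored pair.
#'
#' Methods: `"rwr"` scores a gene by its stationary probability in a
#' restart walk seeded at the disease; `"baseline"` scores it by the
#' hypergeometric overlap between the site neighbourhood of the disease's
#' training genes and the gene's own site neighbourhood (uses only the
#' disease-gene and gene-site links); `"random"` draws i.i.d. uniform
#' scores.
#'
#' @param networks Named list with elements `dd`, `gg`, `ss`, `dg`, `sg`.
#' @param plan A `cv_folds` plan from [make_folds()].
#' @param methods Subset of `c("rwr", "baseline", "random")`.
#' @param r,tol,max_iter RWR parameters.
#' @param negatives `"unassociated"` (default) or `"all_genes"`.
#' @param rng_seed Seed for the random-method scores.
#' @param column_policy Passed to [assemble_hetnet()].
#' @return A `cv_result` with elements `scores` (per-pair tibble),
#'   `overall` (per-method AUC), `per_disease` (per-method, per-disease
#'   AUC) and `roc` (named list of `roc_result`s).
#' @export
cross_validate <- function(networks, plan,
                           methods = c("rwr", "baseline", "random"),
                           r = 0.75, tol = 1e-10, max_iter = 1000L,
                           negatives = c("unassociated", "all_genes"),
                           rng_seed = 1L, column_policy = "redistribute") {
  methods <- match.arg(methods, several.ok = TRUE)
  negatives <- match.arg(negatives)
  if (!inherits(plan, "cv_folds")) abort("`plan` must come from make_folds()")
  net_full <- assemble_hetnet(networks$dd, networks$gg, networks$ss,
                              networks$dg, networks$sg,
                              column_policy = column_policy)
  reg <- net_full$registry
  gene_ids <- reg$node[reg$layer == "gene"]
  dg <- networks$dg
  sg <- networks$sg
  assoc_full <- split(dg$to, dg$from)
  gene_sites <- split(sg$from, factor(sg$to, levels = gene_ids))
  n_sites_total <- length(attr(sg, "universe_a"))
  k <- attr(plan, "k")
  pair_key <- function(a, b) paste(a, b, sep = "\r")

  set.seed(rng_seed)
  rows <- vector("list", 0)
  for (f in seq_len(k)) {
    test <- plan[plan$fold == f, ]
    in_test <- pair_key(dg$from, dg$to) %in% pair_key(test$from, test$to)
    dg_train <- assoc_net(
      tibble(from = dg$from[!in_test], to = dg$to[!in_test], weight = 1),
      "DG", attr(dg, "universe_a"), attr(dg, "universe_b")
    )
    het_f <- assemble_hetnet(networks$dd, networks$gg, networks$ss,
                             dg_train, sg, column_policy = column_policy,
                             registry = reg)
    train_by_d <- split(dg_train$to, dg_train$from)
    for (d in sort(unique(test$from))) {
      pos <- unique(test$to[test$from == d])
      neg <- if (negatives == "unassociated") {
        setdiff(gene_ids, assoc_full[[d]])
      } else {
        setdiff(gene_ids, pos)
      }
      if (!length(pos) || !length(neg)) next
      cand <- c(pos, neg)
      label <- c(rep(1L, length(pos)), rep(0L, length(neg)))
      base <- tibble(fold = f, disease = d, gene = cand, label = label)
      if ("rwr" %in% methods) {
        res <- rwr(het_f, d, r = r, tol = tol, max_iter = max_iter)
        rows[[length(rows) + 1]] <-
          dplyr::mutate(base, method = "rwr",
                        score = unname(res$probabilities[cand]))
      }
      if ("baseline" %in% methods) {
        s_d <- unique(unlist(gene_sites[train_by_d[[d]]], use.names = FALSE))
        sc <- vapply(cand, function(g) {
          gx <- gene_sites[[g]] %||% character()
          1 - hypergeom_pvalue(n_sites_total, length(s_d), length(gx),
                               length(intersect(gx, s_d)))
        }, numeric(1))
        rows[[length(rows) + 1]] <-
          dplyr::mutate(base, method = "baseline", score = unname(sc))
      }
      if ("random" %in% methods) {
        rows[[length(rows) + 1]] <-
          dplyr::mutate(base, method = "random", score = runif(length(cand)))
      }
    }
  }
  scores <- dplyr::bind_rows(rows)
  if (!nrow(scores)) abort("no testable disease-gene pairs in the plan")

  roc_list <- lapply(split(scores, scores$method), function(df) {
    roc_auc(df$score, df$label)
  })
  overall <- purrr::list_rbind(imap(roc_list, function(rr, m) {
    tibble(method = m, auc = rr$auc, n_pairs = rr$n_pos + rr$n_neg)
  }))
  per_disease <- scores |>
    dplyr::group_by(.data$method, .data$disease) |>
    dplyr::summarise(
      n_pos = sum(.data$label == 1), n_neg = sum(.data$label == 0),
      auc = if (sum(.data$label == 1) > 0 && sum(.data$label == 0) > 0)
        roc_auc(.data$score, .data$label)$auc else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$auc))
  structure(
    list(scores = scores, overall = overall, per_disease = per_disease,
         roc = roc_list, negatives = negatives, k = k),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result: ", x$k, "-fold, ", nrow(x$scores), " scored pairs>\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Per-disease AUC table of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with columns `method`, `disease`, `n_pos`, `n_neg`,
#'   `auc`.
#' @export
tidy.cv_result <- function(x, ...) x$per_disease

#' Per-method summary of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with overall AUC plus mean and median per-disease AUC
#'   per method.
#' @export
glance.cv_result <- function(x, ...) {
  pd <- x$per_disease |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_disease_auc = mean(.data$auc),
                     median_disease_auc = median(.data$auc),
                     n_diseases = dplyr::n(), .groups = "drop")
  dplyr::left_join(x$overall, pd, by = "method")
}

#' Host-gene correlation diagnostic
#'
#' Correlates each site's M-value profile with the expression of its host
#' gene across conditions, and builds a permutation null by re-pairing each
#' site with a randomly drawn gene `n_perm` times. Comparing the two
#' distributions shows whether methylation levels track host-gene
#' expression more than a random gene's.
#'
#' @param meth A `meth_profile` whose site table carries `host_gene`.
#' @param expr An `expr_profile` over the same conditions.
#' @param n_perm Number of random re-pairings (default 1000); 0 returns an
#'   empty null matrix.
#' @param rng_seed Integer seed.
#' @return A `host_gene_diag`: tibble `self` (`site_id`, `host_gene`,
#'   `corr`) and numeric matrix `null` (sites x permutations).
#' @export
host_gene_diagnostic <- function(meth, expr, n_perm = 1000, rng_seed = 1L) {
  if (!inherits(meth, "meth_profile")) abort("`meth` must be a meth_profile")
  if (!identical(meth$conditions, expr$conditions)) {
    abort("methylation and expression profiles must share conditions")
  }
  keep <- meth$sites$host_gene %in% expr$ids
  if (!any(keep)) abort("no site has a host gene in the expression profile")
  if (!all(keep)) {
    inform(paste0(sum(!keep), " site(s) skipped: host gene missing from expression"))
  }
  sites <- meth$sites[keep, ]
  M <- meth$values[keep, , drop = FALSE]
  nc <- ncol(M)
  std_rows <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- NA_real_
    (m - mu) / s
  }
  Ms <- std_rows(M)
  Es <- std_rows(expr$values)
  self_corr <- rowSums(Ms * Es[sites$host_gene, , drop = FALSE]) / (nc - 1)
  null <- matrix(NA_real_, nrow(M), max(0, n_perm))
  if (n_perm > 0) {
    set.seed(rng_seed)
    for (j in seq_len(n_perm)) {
      gidx <- sample.int(length(expr$ids), nrow(M), replace = TRUE)
      null[, j] <- rowSums(Ms * Es[gidx, , drop = FALSE]) / (nc - 1)
    }
  }
  rownames(null) <- sites$site_id
  structure(
    list(self = tibble(site_id = sites$site_id, host_gene = sites$host_gene,
                       corr = unname(self_corr)),
         null = null),
    class = "host_gene_diag"
  )
}
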