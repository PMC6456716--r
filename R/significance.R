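#' Degree-preserving randomization of an association network
#'
#' Rewires a network by repeated edge exchange: two edges a-b and c-d are
#' replaced by a-d and c-b when neither new edge already exists and no
#' self-loop would be created. Node sets and every node's degree are
#' preserved exactly; for bipartite networks each endpoint keeps its layer.
#' Edge weights travel with their slot's first endpoint (topology is
#' randomized, the weight multiset per slot is kept), an approximation for
#' weighted within-layer networks.
#'
#' @param net An `assoc_net` with at least 2 edges.
#' @param rng_seed Integer seed; the rewiring is reproducible bit-exact.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return A rewired `assoc_net` with the same attributes. Networks too
#'   rigid to admit any swap are returned unchanged with a warning.
#' @export
edge_swap_randomize <- function(net, rng_seed, swaps_per_edge = 10) {
  if (!inherits(net, "assoc_net")) abort("`net` must be an assoc_net")
  lp <- attr(net, "layer_pair")
  if (nrow(net) < 2) {
    warn("fewer than 2 edges: nothing to swap")
    return(net)
  }
  undirected <- within_layer(lp)
  ua <- attr(net, "universe_a")
  ub <- attr(net, "universe_b")
  if (undirected) {
    ids <- unique(c(ua, ub))
    i <- match(net$from, ids)
    j <- match(net$to, ids)
  } else {
    # disjoint integer ranges keep the two layers apart in the edge keys
    i <- match(net$from, ua)
    j <- length(ua) + match(net$to, ub)
  }
  set.seed(rng_seed)
  res <- edge_swap_cpp(i, j, as.integer(swaps_per_edge * nrow(net)), undirected)
  if (res$n_success == 0) {
    warn("network too rigid to swap: returning an unchanged copy")
    return(net)
  }
  out <- net
  if (undirected) {
    out$from <- ids[res$from]
    out$to <- ids[res$to]
  } else {
    out$from <- ua[res$from]
    out$to <- ub[res$to - length(ua)]
  }
  # re-canonicalize undirected orientation (from < to)
  assoc_copy(out, net)
}

# rebuild an assoc_net keeping the template's metadata
assoc_copy <- function(edges, template) {
  net <- assoc_net(as_tibble(edges), attr(template, "layer_pair"),
                   attr(template, "universe_a"), attr(template, "universe_b"))
  for (a in c("regulation", "n_tested")) {
    if (!is.null(attr(template, a))) attr(net, a) <- attr(template, a)
  }
  net
}

#' Empirical p-value against a permutation null
#'
#' `p = (1 + #\{null >= observed\}) / (K + 1)` for `K` null scores; the +1
#' pseudo-count keeps p strictly positive with finitely many permutations,
#' and ties count against the observation.
#'
#' @param observed Observed score (scalar).
#' @param null_scores Non-empty numeric vector of null scores.
#' @return P-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_scores) {
  if (!length(null_scores)) abort("null_scores must be non-empty")
  (1 + sum(null_scores >= observed)) / (length(null_scores) + 1)
}

#' Hyper- or hypo-methylation direction of a predicted association
#'
#' For each disease gene, correlates the site's M-value profile with the
#' gene's expression across conditions, flipping the sign for genes
#' under-expressed in the disease. A positive median of these signed
#' correlations indicates hyper-methylation under the disease condition, a
#' negative median hypo-methylation; an exact zero median (or no disease
#' gene present in the expression profile) yields `NA`.
#'
#' @param site_profile Numeric M-value vector across conditions.
#' @param disease_genes Character vector of genes associated with the
#'   disease.
#' @param expr An `expr_profile` over the same conditions.
#' @param disease_gene_sign Named vector mapping gene to `"over"` /
#'   `"under"` (missing genes default to `"over"`).
#' @return Tibble with columns `direction` (`"hyper"`, `"hypo"` or `NA`)
#'   and `median_corr`.
#' @export
direction_of_association <- function(site_profile, disease_genes, expr,
                                     disease_gene_sign = NULL) {
  genes <- intersect(disease_genes, expr$ids)
  if (!length(genes)) {
    return(tibble(direction = NA_character_, median_corr = NA_real_))
  }
  if (length(site_profile) != length(expr$conditions)) {
    abort("site profile length must match the expression conditions")
  }
  cors <- vapply(genes, function(g) {
    e <- expr$values[g, ]
    if (sd(e) == 0 || sd(site_profile) == 0) return(NA_real_)
    cor(site_profile, e)
  }, numeric(1))
  sgn <- rep(1, length(genes))
  if (!is.null(disease_gene_sign)) {
    sgn[disease_gene_sign[genes] %in% "under"] <- -1
  }
  med <- median(cors * sgn, na.rm = TRUE)
  if (is.na(med) || med == 0) {
    return(tibble(direction = NA_character_, median_corr = if (is.na(med)) NA_real_ else 0))
  }
  tibble(direction = if (med > 0) "hyper" else "hypo", median_corr = med)
}

#' Empirical significance of RWR predictions by network randomization
#'
#' Builds `n_networks` degree-preserving randomizations of all five
#' sub-networks, reassembles the transition matrix for each, reruns the
#' restart walk from each query disease, and compares every site's real
#' stationary probability to its own null sample (default) or to the
#' pooled null over all sites.
#'
#' @param networks Named list with elements `dd`, `gg`, `ss`, `dg`, `sg`
#'   (`assoc_net`s).
#' @param diseases Character vector of seed disease ids.
#' @param n_networks Number of random networks (default 100).
#' @param rng_seed Integer seed controlling the whole permutation pipeline.
#' @param swaps_per_edge Attempted swaps per edge per network.
#' @param r,tol RWR parameters.
#' @param null `"per_site"` (default) or `"pooled"`.
#' @param column_policy Passed to [assemble_hetnet()].
#' @return Tibble with columns `disease`, `site_id`, `probability`,
#'   `empirical_p`, sorted by disease then decreasing probability.
#' @export
rwr_significance <- function(networks, diseases, n_networks = 100, rng_seed = 1L,
                             swaps_per_edge = 10, r = 0.75, tol = 1e-10,
                             null = c("per_site", "pooled"),
                             column_policy = "redistribute") {
  null <- match.arg(null)
  net0 <- assemble_hetnet(networks$dd, networks$gg, networks$ss,
                          networks$dg, networks$sg, column_policy = column_policy)
  site_ids <- net0$registry$node[net0$registry$layer == "site"]
  observed <- lapply(diseases, function(d) {
    rwr(net0, d, r = r, tol = tol)$probabilities[site_ids]
  })
  names(observed) <- diseases

  seeds <- derive_seeds(rng_seed, n_networks * 5L)
  nulls <- array(NA_real_, dim = c(length(site_ids), n_networks, length(diseases)),
                 dimnames = list(site_ids, NULL, diseases))
  for (k in seq_len(n_networks)) {
    s <- seeds[(k - 1) * 5 + 1:5]
    rnet <- list(
      dd = edge_swap_randomize(networks$dd, s[1], swaps_per_edge),
      gg = edge_swap_randomize(networks$gg, s[2], swaps_per_edge),
      ss = edge_swap_randomize(networks$ss, s[3], swaps_per_edge),
      dg = edge_swap_randomize(networks$dg, s[4], swaps_per_edge),
      sg = edge_swap_randomize(networks$sg, s[5], swaps_per_edge)
    )
    hk <- assemble_hetnet(rnet$dd, rnet$gg, rnet$ss, rnet$dg, rnet$sg,
                          column_policy = column_policy, registry = net0$registry)
    for (d in diseases) {
      nulls[, k, d] <- rwr(hk, d, r = r, tol = tol)$probabilities[site_ids]
    }
  }

  purrr::list_rbind(lapply(diseases, function(d) {
    obs <- observed[[d]]
    p <- vapply(seq_along(site_ids), function(i) {
      ns <- if (null == "per_site") nulls[i, , d] else as.vector(nulls[, , d])
      empirical_pvalue(obs[i], ns)
    }, numeric(1))
    out <- tibble(disease = d, site_id = site_ids,
                  probability = unname(obs), empirical_p = p)
    dplyr::arrange(out, dplyr::desc(.data$probability), .data$site_id)
  }))
}
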