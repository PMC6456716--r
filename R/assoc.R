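#' Association networks between and within node layers
#'
#' An association network is a tibble of weighted edges carrying its layer
#' pair (`DD`, `GG`, `SS`, `DG`, `SG`) and the node universes of both
#' endpoints as attributes. Within-layer networks are undirected and store
#' each edge once with `from < to`.
#'
#' @param edges Tibble with columns `from`, `to`, `weight` (extra columns
#'   are kept).
#' @param layer_pair One of `"DD"`, `"GG"`, `"SS"`, `"DG"`, `"SG"`.
#' @param universe_a,universe_b Character vectors of all node ids eligible
#'   for each side (equal for within-layer networks).
#' @return An `assoc_net` tibble.
#' @export
assoc_net <- function(edges, layer_pair, universe_a, universe_b = universe_a) {
  layer_pair <- match.arg(layer_pair, c("DD", "GG", "SS", "DG", "SG"))
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) abort("edges need `from` and `to` columns")
  if (!"weight" %in% names(edges)) edges$weight <- rep(1, nrow(edges))
  if (nrow(edges)) {
    if (any(edges$weight < 0)) abort("edge weights must be >= 0")
    if (any(edges$from == edges$to) && within_layer(layer_pair)) {
      abort("self-loops are not allowed in within-layer networks")
    }
    bad_a <- setdiff(edges$from, universe_a)
    bad_b <- setdiff(edges$to, universe_b)
    if (length(c(bad_a, bad_b))) {
      abort(paste0("edge endpoints outside the declared universe: ",
                   paste(head(c(bad_a, bad_b), 5), collapse = ", ")))
    }
    if (within_layer(layer_pair)) {
      swap <- edges$from > edges$to
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
    edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  }
  structure(edges,
    class = c("assoc_net", class(tibble())),
    layer_pair = layer_pair,
    universe_a = unique(universe_a),
    universe_b = unique(universe_b)
  )
}

within_layer <- function(layer_pair) layer_pair %in% c("DD", "GG", "SS")

#' @export
print.assoc_net <- function(x, ...) {
  cat("<assoc_net ", attr(x, "layer_pair"), ": ", nrow(x), " edges over ",
      length(attr(x, "universe_a")), " x ", length(attr(x, "universe_b")),
      " nodes>\n", sep = "")
  NextMethod()
}

#' Pearson correlation with Fisher-z asymptotic p-value
#'
#' Computes the Pearson correlation coefficient and its two-sided p-value
#' from the Fisher z-transformation: `z = atanh(r) * sqrt(n - 3)` compared
#' against the standard normal. The Student-t alternative
#' (`method = "t"`) uses `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @param method `"fisher_z"` (default) or `"t"`.
#' @return Tibble with columns `pcc` and `p`; `NA`s with a warning when a
#'   vector is constant.
#' @export
pearson_pvalue <- function(x, y, method = c("fisher_z", "t")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 4) abort("need at least 4 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: correlation undefined, returning NA")
    return(tibble(pcc = NA_real_, p = NA_real_))
  }
  r <- cor(x, y)
  p <- cor_pvalue(r, n, method)
  tibble(pcc = r, p = p)
}

# vectorized p-value for a correlation matrix/vector
cor_pvalue <- function(r, n, method = "fisher_z") {
  if (method == "fisher_z") {
    z <- atanh(pmin(pmax(r, -1), 1)) * sqrt(n - 3)
    2 * pnorm(-abs(z))
  } else {
    tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * pt(-tt, df = n - 2)
  }
}

#' Build a correlation-based association network
#'
#' Tests all node pairs (all unordered pairs within one profile, or all
#' cross pairs between two profiles) for Pearson correlation across
#' conditions, Bonferroni-adjusts the Fisher-z p-values over the number of
#' pairs actually tested, and keeps pairs with adjusted p below `alpha`
#' whose correlation ranks in the top or bottom `pct` percentile of all
#' tested correlations (ties at the threshold kept). The edge weight is
#' `|pcc|`; the sign is retained in the `pcc` column but positive and
#' negative associations are not distinguished in the walk.
#'
#' @param a A profile object or numeric matrix (rows = nodes, columns =
#'   conditions, rownames = node ids).
#' @param b Optional second profile/matrix for a between-layer network;
#'   `NULL` builds a within-layer network over `a`.
#' @param alpha Bonferroni-adjusted significance cut-off (default 0.05).
#' @param pct Top/bottom percentile band of correlations kept (default 10).
#' @param layer_pair Layer label for the resulting network; defaults to
#'   `"SS"` for within-layer and `"SG"` for two-profile calls.
#' @param method P-value flavour, see [pearson_pvalue()].
#' @return An `assoc_net` with columns `from`, `to`, `weight`, `pcc`,
#'   `p_raw`, `p_adj`.
#' @export
build_correlation_network <- function(a, b = NULL, alpha = 0.05, pct = 10,
                                      layer_pair = NULL,
                                      method = c("fisher_z", "t")) {
  method <- match.arg(method)
  A <- profile_matrix(a)
  within <- is.null(b)
  if (is.null(layer_pair)) layer_pair <- if (within) "SS" else "SG"
  B <- if (within) A else profile_matrix(b)
  if (ncol(A) != ncol(B)) abort("profiles must share the same conditions")
  n <- ncol(A)
  if (n < 4) abort("need at least 4 conditions")

  const_a <- apply(A, 1, sd) == 0
  const_b <- if (within) const_a else apply(B, 1, sd) == 0
  if (any(const_a) || any(const_b)) {
    warn(paste0(sum(const_a) + if (within) 0 else sum(const_b),
                " constant row(s) skipped"))
  }
  Ai <- A[!const_a, , drop = FALSE]
  Bi <- B[!const_b, , drop = FALSE]

  empty <- function() {
    assoc_net(tibble(from = character(), to = character(), weight = numeric(),
                     pcc = numeric(), p_raw = numeric(), p_adj = numeric()),
              layer_pair, rownames(A), rownames(B))
  }
  if (within && nrow(Ai) < 2) return(empty())
  if (!within && (nrow(Ai) < 1 || nrow(Bi) < 1)) return(empty())

  C <- cor(t(Ai), t(Bi))
  if (within) {
    idx <- which(upper.tri(C), arr.ind = TRUE)
  } else {
    idx <- which(matrix(TRUE, nrow(C), ncol(C)), arr.ind = TRUE)
  }
  pcc <- C[idx]
  n_pairs <- length(pcc)
  p_raw <- cor_pvalue(pcc, n, method)
  p_adj <- pmin(1, p_raw * n_pairs)
  hi <- pctl(pcc, 100 - pct)
  lo <- pctl(pcc, pct)
  keep <- p_adj < alpha & (pcc >= hi | pcc <= lo)
  if (!any(keep)) {
    warn(paste0("no ", layer_pair, " pair survived the correlation filters"))
    return(empty())
  }
  edges <- tibble(
    from = rownames(C)[idx[keep, 1]],
    to = colnames(C)[idx[keep, 2]],
    weight = abs(pcc[keep]),
    pcc = pcc[keep],
    p_raw = p_raw[keep],
    p_adj = p_adj[keep]
  )
  net <- assoc_net(edges, layer_pair, rownames(A), rownames(B))
  attr(net, "n_tested") <- n_pairs
  net
}

profile_matrix <- function(x) {
  if (inherits(x, "mw_profile")) return(x$values)
  stop_if_not_numeric_matrix(x, "profile")
  if (is.null(rownames(x))) abort("profile matrix needs rownames")
  x
}

#' Jaccard similarity of two MeSH term sets
#'
#' Disease-disease similarity as the number of shared MeSH terms over the
#' size of the union of the two term sets.
#'
#' @param terms_i,terms_j Non-empty character vectors of MeSH terms.
#' @return Similarity in `[0, 1]`.
#' @export
mesh_similarity <- function(terms_i, terms_j) {
  terms_i <- unique(terms_i)
  terms_j <- unique(terms_j)
  if (!length(terms_i) || !length(terms_j)) abort("term sets must be non-empty")
  length(intersect(terms_i, terms_j)) / length(union(terms_i, terms_j))
}

#' Build the disease-disease similarity network from MeSH annotations
#'
#' Computes pairwise Jaccard similarity of MeSH term sets for all disease
#' pairs; no similarity cut-off is applied, but zero-similarity pairs are
#' stored as absent edges (equivalent under column normalization).
#'
#' @param disease_terms Data frame with columns `disease` and `term`, one
#'   term per row.
#' @return An `assoc_net` with `layer_pair = "DD"`.
#' @export
build_disease_network <- function(disease_terms) {
  disease_terms <- as_tibble(disease_terms)
  names(disease_terms)[1:2] <- c("disease", "term")
  disease_terms <- dplyr::filter(disease_terms, !is.na(.data$term), .data$term != "")
  term_sets <- split(disease_terms$term, disease_terms$disease)
  term_sets <- lapply(term_sets, unique)
  empty <- names(term_sets)[lengths(term_sets) == 0]
  if (length(empty)) {
    warn(paste0("diseases with no MeSH terms excluded: ", paste(empty, collapse = ", ")))
    term_sets <- term_sets[lengths(term_sets) > 0]
  }
  ids <- sort(names(term_sets))
  if (length(ids) < 2) abort("need at least 2 diseases with terms")
  pairs <- utils::combn(ids, 2)
  w <- vapply(seq_len(ncol(pairs)), function(k) {
    mesh_similarity(term_sets[[pairs[1, k]]], term_sets[[pairs[2, k]]])
  }, numeric(1))
  keep <- w > 0
  assoc_net(
    tibble(from = pairs[1, keep], to = pairs[2, keep], weight = w[keep]),
    "DD", ids
  )
}

#' Load a disease-gene association list
#'
#' Reads a two-column id-pair table (disease, gene) into an unweighted
#' bipartite network; duplicate pairs collapse to a single edge. An
#' optional third column of regulation labels (`over` / `under`) is kept in
#' a `regulation` attribute for the direction-of-association step.
#'
#' @param x Path to a TSV file (header or not) or a data frame.
#' @return An `assoc_net` with `layer_pair = "DG"` and weight 1 edges.
#' @export
load_disease_gene <- function(x) {
  if (is.character(x) && length(x) == 1) {
    df <- utils::read.delim(x, header = TRUE, colClasses = "character")
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (!nrow(df)) {
    warn("empty disease-gene table")
    return(assoc_net(tibble(from = character(), to = character(), weight = numeric()),
                     "DG", character(), character()))
  }
  if (ncol(df) < 2) abort("disease-gene table needs two columns")
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]) | df[[1]] == "" | df[[2]] == "")
  if (length(bad)) abort(paste0("malformed disease-gene row(s): line ",
                                paste(head(bad, 5), collapse = ", ")))
  edges <- tibble(from = as.character(df[[1]]), to = as.character(df[[2]]), weight = 1)
  net <- assoc_net(edges, "DG", unique(edges$from), unique(edges$to))
  if (ncol(df) >= 3) {
    reg <- tibble(disease = as.character(df[[1]]), gene = as.character(df[[2]]),
                  regulation = as.character(df[[3]]))
    attr(net, "regulation") <- dplyr::distinct(reg)
  }
  net
}

#' Write / read association network edge lists
#'
#' Edge lists are exchanged as TSV with columns `from`, `to`, `weight`.
#'
#' @param net An `assoc_net`.
#' @param path File path.
#' @rdname edge-io
#' @export
write_edges <- function(net, path) {
  readr::write_tsv(as_tibble(net), path)
  invisible(path)
}

#' @param layer_pair,universe_a,universe_b Metadata for the loaded network
#'   (universes default to the endpoint ids present in the file).
#' @rdname edge-io
#' @export
read_edges <- function(path, layer_pair, universe_a = NULL, universe_b = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ua <- universe_a %||% unique(df$from)
  ub <- universe_b %||% if (within_layer(layer_pair)) ua else unique(df$to)
  if (within_layer(layer_pair)) ua <- ub <- unique(c(ua, ub, df$from, df$to))
  assoc_net(df, layer_pair, ua, ub)
}
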