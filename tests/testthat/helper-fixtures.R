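# Shared fixture builders. Everything is generated in code under explicit
# seeds; no data files.

# wrap an arbitrary transition matrix as a hetnet so rwr()/rwr_solve() can
# be exercised outside the block-assembly path
hetnet_from_W <- function(W, layers = NULL) {
  n <- nrow(W)
  nodes <- sprintf("n%04d", seq_len(n))
  W <- methods::as(Matrix::Matrix(W, sparse = TRUE), "CsparseMatrix")
  dimnames(W) <- list(nodes, nodes)
  reg <- tibble::tibble(node = nodes,
                        layer = layers %||% rep("site", n),
                        index = seq_len(n))
  structure(list(registry = reg, W = W, column_policy = "redistribute",
                 block_weights = NULL),
            class = "hetnet")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random sparse column-stochastic matrix (every column nonzero)
random_stochastic_W <- function(n, density = 0.02, seed = 1) {
  set.seed(seed)
  W <- abs(Matrix::rsparsematrix(n, n, density))
  W <- W + Matrix::Diagonal(n, runif(n, 0.1, 1))
  column_normalize(W)
}

# random bipartite assoc_net with n_a x n_b nodes and m distinct edges
random_bipartite_net <- function(n_a, n_b, m, layer_pair = "DG", seed = 1) {
  set.seed(seed)
  ua <- sprintf("a%03d", seq_len(n_a))
  ub <- sprintf("b%03d", seq_len(n_b))
  pairs <- unique(data.frame(
    from = sample(ua, 3 * m, replace = TRUE),
    to = sample(ub, 3 * m, replace = TRUE)
  ))[seq_len(m), ]
  assoc_net(tibble::tibble(from = pairs$from, to = pairs$to, weight = 1),
            layer_pair, ua, ub)
}

# random undirected weighted assoc_net
random_within_net <- function(n, m, layer_pair = "GG", seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- t(combn(ids, 2))
  take <- sample(nrow(pairs), m)
  assoc_net(tibble::tibble(from = pairs[take, 1], to = pairs[take, 2],
                           weight = runif(m, 0.2, 1)),
            layer_pair, ids)
}

# tiny five-network fixture with consistent universes
toy_networks <- function(seed = 1) {
  set.seed(seed)
  diseases <- c("dA", "dB", "dC")
  genes <- sprintf("g%02d", 1:6)
  sites <- sprintf("s%02d", 1:8)
  dd <- assoc_net(tibble::tibble(from = c("dA", "dA"), to = c("dB", "dC"),
                                 weight = c(0.5, 0.2)), "DD", diseases)
  gg <- assoc_net(tibble::tibble(from = c("g01", "g02", "g03"),
                                 to = c("g02", "g03", "g04"),
                                 weight = c(0.9, 0.8, 0.7)), "GG", genes)
  ss <- assoc_net(tibble::tibble(from = c("s01", "s02"), to = c("s02", "s03"),
                                 weight = c(0.9, 0.6)), "SS", sites)
  dg <- assoc_net(tibble::tibble(from = c("dA", "dA", "dB", "dC"),
                                 to = c("g01", "g02", "g03", "g05"),
                                 weight = 1), "DG", diseases, genes)
  sg <- assoc_net(tibble::tibble(from = c("s01", "s02", "s04", "s05"),
                                 to = c("g01", "g02", "g03", "g05"),
                                 weight = c(0.9, 0.8, 0.9, 0.7)),
                  "SG", sites, genes)
  list(dd = dd, gg = gg, ss = ss, dg = dg, sg = sg)
}

# degree tally that ignores edge orientation for within-layer networks
degree_table <- function(net) {
  if (attr(net, "layer_pair") %in% c("DD", "GG", "SS")) {
    sort(table(c(net$from, net$to)))
  } else {
    list(a = sort(table(net$from)), b = sort(table(net$to)))
  }
}

# brute-force all-pairs Mann-Whitney AUC with half credit for ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# hypergeometric upper tail by exhaustive enumeration of all size-n draws
hyper_tail_enum <- function(m, n, x, y) {
  if (y == 0) return(1)
  if (n == 0) return(0)
  draws <- combn(m, n)
  hits <- colSums(draws <= x)  # successes are items 1..x
  mean(hits >= y)
}

small_study <- function(seed = 7) {
  simulate_study(synth_config(
    n_diseases = 8, n_genes = 60, n_sites = 120, n_conditions = 20,
    n_modules = 4, rng_seed = seed
  ))
}
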