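#' Column-normalize a non-negative matrix
#'
#' Divides each column by its sum so that every nonzero column sums to 1;
#' all-zero columns are left unchanged.
#'
#' @param block Non-negative numeric matrix or sparse `Matrix`.
#' @return Matrix of the same class and shape.
#' @export
column_normalize <- function(block) {
  if (any(block < 0)) abort("entries must be >= 0")
  cs <- Matrix::colSums(block)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  block %*% Matrix::Diagonal(x = scale)
}

# sparse symmetric adjacency from a within-layer assoc_net
adj_within <- function(net, ids) {
  n <- length(ids)
  if (!nrow(net)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(), dims = c(n, n),
                                              dimnames = list(ids, ids)))
  i <- match(net$from, ids)
  j <- match(net$to, ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(net$from[is.na(i)], net$to[is.na(j)]))
    abort(paste0("unknown node id in edges: ", paste(head(bad, 5), collapse = ", ")))
  }
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(net$weight, 2),
                       dims = c(n, n), dimnames = list(ids, ids))
}

# sparse bipartite incidence (rows = ids_a, cols = ids_b)
adj_between <- function(net, ids_a, ids_b) {
  if (!nrow(net)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                              x = numeric(),
                                              dims = c(length(ids_a), length(ids_b)),
                                              dimnames = list(ids_a, ids_b)))
  i <- match(net$from, ids_a)
  j <- match(net$to, ids_b)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(net$from[is.na(i)], net$to[is.na(j)]))
    abort(paste0("unknown node id in edges: ", paste(head(bad, 5), collapse = ", ")))
  }
  Matrix::sparseMatrix(i = i, j = j, x = net$weight,
                       dims = c(length(ids_a), length(ids_b)),
                       dimnames = list(ids_a, ids_b))
}

#' Assemble the heterogeneous-network transition matrix
#'
#' Stacks the five association sub-networks into one column-normalized
#' block transition matrix over the node ordering (diseases, genes, sites).
#' Each sub-block is column-normalized independently and scaled by its
#' equal-weight share: disease columns split 1/2 : 1/2 between
#' disease-disease and disease-gene transitions, gene columns 1/3 : 1/3 :
#' 1/3 between gene-disease, gene-gene and gene-site, and site columns
#' 1/2 : 1/2 between site-gene and site-site. The disease-site block is a
#' structural zero (no prior disease-site knowledge). When a node has no
#' edges of one type, `column_policy = "redistribute"` (default) reassigns
#' that block's weight proportionally to the node's remaining blocks so the
#' column still sums to 1; `"leak"` keeps the nominal weights and lets the
#' column sum fall short. Fully isolated nodes keep a zero column.
#'
#' @param dd,gg,ss Within-layer `assoc_net`s (disease, gene, site).
#' @param dg Disease-gene bipartite `assoc_net` (`from` = disease).
#' @param sg Site-gene bipartite `assoc_net` (`from` = site).
#' @param column_policy `"redistribute"` or `"leak"`, see above.
#' @param registry Optional pre-built node registry (tibble with columns
#'   `node`, `layer`); defaults to the sorted union of ids seen in the
#'   networks' universes.
#' @return A `hetnet` object: node registry plus sparse transition matrix
#'   `W`.
#' @export
assemble_hetnet <- function(dd, gg, ss, dg, sg,
                            column_policy = c("redistribute", "leak"),
                            registry = NULL) {
  column_policy <- match.arg(column_policy)
  if (is.null(registry)) {
    diseases <- sort(unique(c(attr(dd, "universe_a"), attr(dg, "universe_a"))))
    genes <- sort(unique(c(attr(gg, "universe_a"), attr(dg, "universe_b"),
                           attr(sg, "universe_b"))))
    sites <- sort(unique(c(attr(ss, "universe_a"), attr(sg, "universe_a"))))
  } else {
    diseases <- registry$node[registry$layer == "disease"]
    genes <- registry$node[registry$layer == "gene"]
    sites <- registry$node[registry$layer == "site"]
  }
  overlap <- intersect(intersect(diseases, genes), sites)
  if (length(intersect(diseases, genes)) || length(intersect(genes, sites)) ||
      length(intersect(diseases, sites))) {
    abort("node ids must be unique across layers")
  }
  N <- length(diseases); T_ <- length(genes); M <- length(sites)

  A_dd <- adj_within(dd, diseases)
  A_gg <- adj_within(gg, genes)
  A_ss <- adj_within(ss, sites)
  B_dg <- adj_between(dg, diseases, genes)   # disease rows x gene cols
  B_sg <- adj_between(sg, sites, genes)      # site rows x gene cols

  # column-normalized blocks, named <row layer><col layer>
  nDD <- column_normalize(A_dd)              # D x D
  nGD <- column_normalize(Matrix::t(B_dg))   # gene rows x disease cols
  nDG <- column_normalize(B_dg)              # disease rows x gene cols
  nGG <- column_normalize(A_gg)
  nSG <- column_normalize(B_sg)              # site rows x gene cols
  nGS <- column_normalize(Matrix::t(B_sg))   # gene rows x site cols
  nSS <- column_normalize(A_ss)

  # per-column block weights with optional redistribution
  block_scales <- function(present, base) {
    # present: list of logical vectors (block has mass in that column)
    # base: nominal weights
    pres <- do.call(cbind, present)
    basew <- matrix(base, nrow = nrow(pres), ncol = length(base), byrow = TRUE)
    if (column_policy == "redistribute") {
      tot <- rowSums(basew * pres)
      sc <- ifelse(pres & tot > 0, basew / tot, 0)
    } else {
      sc <- basew * pres
    }
    sc
  }

  d_pres <- list(dd = Matrix::colSums(A_dd) > 0, dg = Matrix::colSums(Matrix::t(B_dg)) > 0)
  d_sc <- block_scales(d_pres, c(1 / 2, 1 / 2))
  g_pres <- list(gd = Matrix::colSums(B_dg) > 0, gg = Matrix::colSums(A_gg) > 0,
                 gs = Matrix::colSums(B_sg) > 0)
  g_sc <- block_scales(g_pres, c(1 / 3, 1 / 3, 1 / 3))
  s_pres <- list(sg = Matrix::colSums(Matrix::t(B_sg)) > 0, ss = Matrix::colSums(A_ss) > 0)
  s_sc <- block_scales(s_pres, c(1 / 2, 1 / 2))

  scale_cols <- function(m, s) m %*% Matrix::Diagonal(x = s)
  zero <- function(nr, nc) Matrix::sparseMatrix(i = integer(), j = integer(),
                                                x = numeric(), dims = c(nr, nc))

  W <- rbind(
    cbind(scale_cols(nDD, d_sc[, 1]), scale_cols(nDG, g_sc[, 1]), zero(N, M)),
    cbind(scale_cols(nGD, d_sc[, 2]), scale_cols(nGG, g_sc[, 2]), scale_cols(nGS, s_sc[, 1])),
    cbind(zero(M, N), scale_cols(nSG, g_sc[, 3]), scale_cols(nSS, s_sc[, 2]))
  )
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  nodes <- c(diseases, genes, sites)
  dimnames(W) <- list(nodes, nodes)

  reg <- tibble(
    node = nodes,
    layer = rep(c("disease", "gene", "site"), times = c(N, T_, M)),
    index = seq_along(nodes)
  )
  structure(
    list(registry = reg, W = W, column_policy = column_policy,
         block_weights = c(DD = 1 / 2, DG = 1 / 2, GD = 1 / 3, GG = 1 / 3,
                           GS = 1 / 3, SG = 1 / 2, SS = 1 / 2)),
    class = "hetnet"
  )
}

#' @export
print.hetnet <- function(x, ...) {
  n <- table(factor(x$registry$layer, levels = c("disease", "gene", "site")))
  cat("<hetnet: ", n[["disease"]], " diseases, ", n[["gene"]], " genes, ",
      n[["site"]], " sites; ", Matrix::nnzero(x$W), " transitions>\n", sep = "")
  invisible(x)
}

#' Tidy the heterogeneous network into an edge tibble
#'
#' @param x A `hetnet`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `probability` (transition
#'   probability out of `from`).
#' @export
tidy.hetnet <- function(x, ...) {
  trip <- Matrix::summary(x$W)
  tibble(
    from = x$registry$node[trip$j],
    to = x$registry$node[trip$i],
    probability = trip$x
  )
}

#' Serialize / load a heterogeneous network
#'
#' Writes the node registry (TSV), the sparse transition matrix in triplet
#' form (TSV: `row_id`, `col_id`, `value`) and a JSON sidecar with the
#' block weights and column policy.
#'
#' @param net A `hetnet`.
#' @param dir Directory to write into (created if missing).
#' @rdname hetnet-io
#' @export
write_hetnet <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(net$registry, file.path(dir, "registry.tsv"))
  trip <- Matrix::summary(net$W)
  readr::write_tsv(
    tibble(row_id = net$registry$node[trip$i],
           col_id = net$registry$node[trip$j],
           value = trip$x),
    file.path(dir, "transitions.tsv")
  )
  jsonlite::write_json(
    list(column_policy = net$column_policy,
         block_weights = as.list(net$block_weights)),
    file.path(dir, "hetnet.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname hetnet-io
#' @export
read_hetnet <- function(dir) {
  reg <- readr::read_tsv(file.path(dir, "registry.tsv"), show_col_types = FALSE,
                         progress = FALSE)
  trip <- readr::read_tsv(file.path(dir, "transitions.tsv"), show_col_types = FALSE,
                          progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "hetnet.json"))
  n <- nrow(reg)
  W <- Matrix::sparseMatrix(
    i = match(trip$row_id, reg$node), j = match(trip$col_id, reg$node),
    x = trip$value, dims = c(n, n), dimnames = list(reg$node, reg$node)
  )
  structure(
    list(registry = as_tibble(reg), W = W,
         column_policy = meta$column_policy,
         block_weights = unlist(meta$block_weights)),
    class = "hetnet"
  )
}
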