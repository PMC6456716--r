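#' Random walk with restart over the heterogeneous network
#'
#' Iterates `P <- (1 - r) * W %*% P + r * P0` from an indicator vector on
#' the seed node until the difference between successive probability
#' vectors falls at or below `tol` (L-infinity norm by default), or
#' `max_iter` is reached. With restart probability `r = 0.75` and a
#' column-stochastic `W` the iteration contracts by a factor `1 - r` per
#' step, so convergence is fast regardless of network size.
#'
#' @param net A `hetnet`.
#' @param seed Node id to restart to (any layer; for disease-site
#'   prioritisation, a disease node).
#' @param r Restart probability in (0, 1), default 0.75.
#' @param tol Convergence threshold on the step difference, default 1e-10.
#' @param max_iter Iteration cap, default 1000; hitting it flags
#'   `converged = FALSE` rather than erroring.
#' @param norm `"linf"` (default) or `"l1"` step-difference norm.
#' @return An `rwr_result`: named probability vector over all nodes,
#'   iteration count, convergence flag and the seed id.
#' @export
rwr <- function(net, seed, r = 0.75, tol = 1e-10, max_iter = 1000L,
                norm = c("linf", "l1")) {
  norm <- match.arg(norm)
  check_rwr_args(net, seed, r, tol)
  nodes <- net$registry$node
  p0 <- numeric(length(nodes))
  p0[match(seed, nodes)] <- 1
  W <- net$W
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- as.numeric((1 - r) * (W %*% p)) + r * p0
    delta <- if (norm == "linf") max(abs(p_new - p)) else sum(abs(p_new - p))
    p <- p_new
    if (delta <= tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(probabilities = setNames(p, nodes), iterations = iter,
         converged = converged, seed_id = seed, r = r, registry = net$registry),
    class = "rwr_result"
  )
}

check_rwr_args <- function(net, seed, r, tol) {
  if (!inherits(net, "hetnet")) abort("`net` must be a hetnet")
  if (!(seed %in% net$registry$node)) abort(paste0("seed node not in registry: ", seed))
  if (!(r > 0 && r < 1)) abort("restart probability must lie in (0, 1)")
  if (tol <= 0) abort("tol must be > 0")
}

#' Closed-form fixed point of the restart walk
#'
#' Solves the stationary equation directly,
#' `P = r * (I - (1 - r) W)^{-1} P0`, by a sparse linear solve. Intended as
#' an exact oracle at test scale (the system is non-singular whenever
#' `r > 0` and `W` is column-(sub)stochastic).
#'
#' @inheritParams rwr
#' @return Named numeric vector of stationary probabilities.
#' @export
rwr_solve <- function(net, seed, r = 0.75) {
  check_rwr_args(net, seed, r, 1e-10)
  nodes <- net$registry$node
  n <- length(nodes)
  p0 <- numeric(n)
  p0[match(seed, nodes)] <- 1
  A <- Matrix::Diagonal(n) - (1 - r) * net$W
  p <- as.numeric(Matrix::solve(A, r * p0))
  setNames(p, nodes)
}

#' Rank m6A sites by stationary probability
#'
#' Extracts the site-layer entries of an RWR result, sorted by decreasing
#' probability; ties break lexicographically on the site id so the ranking
#' is deterministic.
#'
#' @param result An `rwr_result`.
#' @param registry Optional node registry (defaults to the one stored in
#'   the result).
#' @param layer Which layer to rank, default `"site"`.
#' @return Tibble with columns `site_id`, `probability`, `rank`.
#' @export
rank_sites <- function(result, registry = NULL, layer = "site") {
  registry <- registry %||% result$registry
  ids <- registry$node[registry$layer == layer]
  p <- result$probabilities[ids]
  out <- tibble(site_id = ids, probability = unname(p))
  out <- dplyr::arrange(out, dplyr::desc(.data$probability), .data$site_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("<rwr_result: seed ", x$seed_id, ", r = ", x$r, ", ",
      x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ">\n", sep = "")
  invisible(x)
}

#' Tidy an RWR result
#'
#' @param x An `rwr_result`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `layer`, `probability`.
#' @export
tidy.rwr_result <- function(x, ...) {
  tibble(
    node = names(x$probabilities),
    layer = x$registry$layer[match(names(x$probabilities), x$registry$node)],
    probability = unname(x$probabilities)
  )
}

#' One-line summary of an RWR run
#'
#' @param x An `rwr_result`.
#' @param ... Unused.
#' @return Tibble with seed, restart probability, iterations, convergence
#'   flag and total probability mass.
#' @export
glance.rwr_result <- function(x, ...) {
  tibble(
    seed_id = x$seed_id, r = x$r, iterations = x$iterations,
    converged = x$converged, total_mass = sum(x$probabilities)
  )
}
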