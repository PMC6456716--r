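# internal helpers shared across modules

# percentile with linear interpolation between order statistics (quantile
# type 7); `p` on the 0-100 scale used throughout the interface
pctl <- function(x, p) {
  stats::quantile(x, p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

stop_if_not_numeric_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(paste0("`", what, "` must be a numeric matrix"))
  }
}

# coerce a tibble/data.frame whose first column holds row ids (or a matrix
# with rownames) into a numeric matrix with rownames
as_id_matrix <- function(x, what = "table") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort(paste0("`", what, "` matrix needs rownames"))
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) abort(paste0("`", what, "` must be a data frame or matrix"))
  if (ncol(x) < 2) abort(paste0("`", what, "` needs an id column plus value columns"))
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids)) abort(paste0("duplicate row ids in `", what, "`"))
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# deterministic child seeds below 2^31, derived from a user seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
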