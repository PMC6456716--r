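test_that("m_value matches the log2 pseudo-count ratio and rejects bad input", {
  expect_equal(m_value(1.9, 0.9), 1)
  expect_equal(m_value(0, 0.9), log2(0.1 / 1.0))
  for (x in c(0, 0.3, 5, 123.4)) expect_equal(m_value(x, x), 0)
  expect_error(m_value(-1, 2), "RPKM")
  expect_error(m_value(1, -2), "RPKM")
  expect_error(m_value(NA_real_, 1), "NA")
})

test_that("m_value is increasing in IP and decreasing in Input", {
  ip <- seq(0, 50, length.out = 40)
  expect_true(all(diff(m_value(ip, 3)) > 0))
  expect_true(all(diff(m_value(3, ip)) < 0))
})

test_that("merge_replicates averages within groups in first-appearance order", {
  tbl <- tibble::tibble(id = c("r1", "r2"),
                        c1a = c(4, 0), c1b = c(6, 0), c2 = c(1, 3))
  map <- data.frame(condition_id = c("c1a", "c1b", "c2"),
                    group = c("c1", "c1", "c2"))
  out <- merge_replicates(tbl, map)
  expect_equal(names(out), c("id", "c1", "c2"))
  expect_equal(out$c1, c(5, 0))
  expect_equal(out$c2, c(1, 3))

  # single-replicate group passes through unchanged
  expect_equal(out$c2, tbl$c2)

  # three replicates, arithmetic mean
  tbl3 <- tibble::tibble(id = "r1", a = 0, b = 0, c = 3)
  map3 <- data.frame(condition_id = c("a", "b", "c"), group = "g")
  expect_equal(merge_replicates(tbl3, map3)$g, 1)

  # unmapped column and empty group are errors
  expect_error(merge_replicates(tbl, map[-3, ]), "without a replicate group")
})

test_that("merge then m_value equals m_value of merged values", {
  set.seed(1)
  ip <- matrix(runif(12, 0, 20), 3, dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c", "d")[1:4]))
  input <- matrix(runif(12, 0, 20), 3, dimnames = dimnames(ip))
  map <- data.frame(condition_id = colnames(ip), group = c("x", "x", "y", "y"))
  mi <- as.matrix(merge_replicates(ip, map)[-1])
  mn <- as.matrix(merge_replicates(input, map)[-1])
  expect_equal(m_value(mi, mn), log2((mi + 0.1) / (mn + 0.1)))
})

test_that("quantile_normalize equalizes column value multisets", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("r", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- cbind(x = c(3, 1, 7), y = c(3, 1, 7))
  rownames(m2) <- paste0("r", 1:3)
  expect_equal(quantile_normalize(m2), m2, ignore_attr = FALSE)

  # defining property on a random matrix: identical sorted columns,
  # preserved within-column ranks, equal column means
  set.seed(42)
  m3 <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("r", 1:12), paste0("c", 1:5)))
  qn3 <- quantile_normalize(m3)
  sorted <- apply(qn3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_true(all(abs(colMeans(qn3) - mean(colMeans(qn3))) < 1e-12))
  for (j in 1:5) expect_equal(rank(qn3[, j]), rank(m3[, j]))

  expect_error(quantile_normalize(m[, 1, drop = FALSE]), ">= 2 columns")
})

make_toy_profile <- function() {
  # 10 sites with controlled support, means and variances
  set.seed(11)
  n <- 10
  cond <- paste0("c", 1:6)
  m <- matrix(rnorm(n * 6), n, 6, dimnames = list(sprintf("s%02d", 1:n), cond))
  m <- m * seq(0.2, 2, length.out = n)       # spread of variances
  m <- m + seq(-1, 2.5, length.out = n)      # spread of means
  sites <- tibble::tibble(
    site_id = rownames(m), chrom = "chr1",
    start = 1:n * 1000L, end = 1:n * 1000L + 101L, strand = "+",
    host_gene = sprintf("g%02d", 1:n),
    support_count = c(5L, 10L, 11L, 15L, 20L, 25L, 30L, 12L, 40L, 9L)
  )
  structure(list(ids = rownames(m), conditions = cond, values = m, sites = sites),
            class = c("meth_profile", "mw_profile"))
}

test_that("filter_sites applies strict support, level and variance rules in order", {
  prof <- make_toy_profile()
  out <- filter_sites(prof, min_support = 10, level_pct = 70, var_pct = 80)

  # independent step-by-step recomputation of the survivor list
  keep1 <- prof$sites$support_count > 10
  m1 <- prof$values[keep1, ]
  mu <- rowMeans(m1)
  keep2 <- mu <= quantile(mu, 0.70, type = 7)
  m2 <- m1[keep2, ]
  v <- apply(m2, 1, var)
  keep3 <- v >= quantile(v, 1 - 0.80, type = 7)
  expected <- rownames(m2)[keep3]
  expect_equal(out$ids, expected)

  # support_count == 10 must be removed (strict >)
  expect_false("s02" %in% out$ids)

  # the strict support rule is idempotent (percentile steps re-trim by
  # construction, so idempotence holds only for the support filter and in
  # all-tied profiles; see the degenerate-case test below)
  again <- filter_sites(out, min_support = 10, level_pct = 100, var_pct = 100)
  expect_equal(again$ids, out$ids)

  # subset property
  expect_true(all(out$ids %in% prof$ids))
})

test_that("filter_sites keeps everything tied at the variance threshold", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4,
              dimnames = list(sprintf("s%d", 1:5), paste0("c", 1:4)))
  sites <- tibble::tibble(site_id = rownames(m), chrom = "chr1",
                          start = 1:5, end = 2:6, strand = "+",
                          host_gene = "g", support_count = 20L)
  prof <- structure(list(ids = rownames(m), conditions = colnames(m),
                         values = m, sites = sites),
                    class = c("meth_profile", "mw_profile"))
  out <- filter_sites(prof)
  # identical profiles: every mean and variance ties at its threshold, all kept
  expect_equal(nrow(out$values), 5)
  # and in this all-tied case the filter is idempotent
  expect_equal(filter_sites(out)$ids, out$ids)
})

test_that("filter_sites errors with diagnostics when nothing survives", {
  prof <- make_toy_profile()
  expect_error(filter_sites(prof, min_support = 100), "all sites filtered out")
})

test_that("build_methylation_profile composes merge, M-value and normalization", {
  study <- small_study()
  prof <- build_methylation_profile(study$site_ip, study$site_input,
                                    study$sites, study$replicate_map)
  expect_s3_class(prof, "meth_profile")
  expect_equal(length(prof$conditions), study$config$n_conditions)
  expect_true(all(is.finite(prof$values)))
  # quantile normalization leaves identical sorted columns
  sorted <- apply(prof$values, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
})
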