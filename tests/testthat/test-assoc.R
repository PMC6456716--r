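test_that("pearson_pvalue reproduces the Fisher-z normal test", {
  # frozen hand evaluation: z = atanh(0.5) * sqrt(38 - 3)
  set.seed(3)
  x <- rnorm(38)
  # construct y with exact sample correlation 0.5
  xs <- scale(x)[, 1]
  e <- scale(resid(lm(rnorm(38) ~ xs)))[, 1]
  y <- 0.5 * xs + sqrt(1 - 0.25) * e
  res <- pearson_pvalue(x, y)
  expect_equal(res$pcc, 0.5, tolerance = 1e-12)
  expect_equal(res$p, 0.0011551098, tolerance = 1e-7)

  # perfect correlation
  res1 <- pearson_pvalue(x, 2 * x + 1)
  expect_equal(res1$pcc, 1)
  expect_equal(res1$p, 0)

  # constant vector: NA with warning
  expect_warning(res_na <- pearson_pvalue(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res_na$pcc))
  expect_error(pearson_pvalue(1:3, 1:3), "at least 4")
})

test_that("Fisher-z p-values are approximately uniform under the null", {
  set.seed(99)
  p <- replicate(1000, pearson_pvalue(rnorm(38), rnorm(38))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("build_correlation_network matches a brute-force pair-by-pair oracle", {
  # 6 rows, two planted correlated blocks of 3
  set.seed(5)
  n <- 12
  f1 <- rnorm(n); f2 <- rnorm(n)
  A <- rbind(
    f1 + 0.1 * rnorm(n), f1 + 0.1 * rnorm(n), f1 + 0.1 * rnorm(n),
    f2 + 0.1 * rnorm(n), f2 + 0.1 * rnorm(n), f2 + 0.1 * rnorm(n)
  )
  rownames(A) <- sprintf("r%d", 1:6)
  pct <- 40
  alpha <- 0.05
  net <- build_correlation_network(A, alpha = alpha, pct = pct, layer_pair = "SS")

  # oracle: test all 15 pairs explicitly
  pairs <- t(combn(rownames(A), 2))
  pcc <- apply(pairs, 1, function(pr) cor(A[pr[1], ], A[pr[2], ]))
  p_raw <- 2 * pnorm(-abs(atanh(pcc)) * sqrt(n - 3))
  p_adj <- pmin(1, p_raw * nrow(pairs))
  hi <- quantile(pcc, 1 - pct / 100, type = 7)
  lo <- quantile(pcc, pct / 100, type = 7)
  kept <- p_adj < alpha & (pcc >= hi | pcc <= lo)
  oracle_edges <- sort(paste(pairs[kept, 1], pairs[kept, 2]))
  got_edges <- sort(paste(net$from, net$to))
  expect_equal(got_edges, oracle_edges)

  # exactly the within-block pairs survive
  blocks <- sort(c("r1 r2", "r1 r3", "r2 r3", "r4 r5", "r4 r6", "r5 r6"))
  expect_equal(got_edges, blocks)

  # weight is |pcc|, Bonferroni never lowers the raw p
  expect_equal(net$weight, abs(net$pcc))
  expect_true(all(net$p_adj >= net$p_raw))
  expect_true(all(net$p_adj < alpha))
})

test_that("correlation networks are invariant to input row order", {
  set.seed(6)
  A <- matrix(rnorm(8 * 15), 8, dimnames = list(sprintf("r%d", 1:8), NULL))
  A[2, ] <- A[1, ] + 0.05 * rnorm(15)
  n1 <- build_correlation_network(A, pct = 30, layer_pair = "GG")
  n2 <- build_correlation_network(A[sample(8), ], pct = 30, layer_pair = "GG")
  key <- function(net) {
    df <- as.data.frame(net)[order(net$from, net$to), c("from", "to", "weight")]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(n1), key(n2))
})

test_that("familywise error stays controlled on pure-noise profiles", {
  hits <- 0
  for (s in 1:200) {
    set.seed(s)
    A <- matrix(rnorm(8 * 20), 8, dimnames = list(sprintf("r%d", 1:8), NULL))
    net <- suppressWarnings(
      build_correlation_network(A, alpha = 0.05, pct = 100, layer_pair = "GG")
    )
    if (nrow(net) > 0) hits <- hits + 1
  }
  # FWER <= 0.05 => expect <= ~10 of 200; generous binomial slack
  expect_lte(hits, 25)
})

test_that("mesh_similarity is the Jaccard index", {
  expect_equal(mesh_similarity(c("A", "B"), c("A", "B")), 1)
  expect_equal(mesh_similarity(c("A", "B"), c("C", "D")), 0)
  expect_equal(mesh_similarity(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(mesh_similarity(c("A", "B"), c("B", "C")),
               mesh_similarity(c("B", "C"), c("A", "B")))
  expect_error(mesh_similarity(character(), "A"), "non-empty")
})

test_that("build_disease_network computes all pairwise Jaccard weights", {
  terms <- tibble::tibble(
    disease = rep(c("d1", "d2", "d3"), times = c(2, 2, 3)),
    term = c("A", "B", "B", "C", "A", "B", "C")
  )
  net <- build_disease_network(terms)
  w <- setNames(net$weight, paste(net$from, net$to))
  expect_equal(unname(w["d1 d2"]), 1 / 3)
  expect_equal(unname(w["d1 d3"]), 2 / 3)
  expect_equal(unname(w["d2 d3"]), 2 / 3)
  expect_lte(nrow(net), 3 * 2 / 2)

  # identical term sets give weight-1 complete graph
  same <- tibble::tibble(disease = rep(c("x", "y", "z"), each = 2),
                         term = rep(c("T1", "T2"), 3))
  net2 <- build_disease_network(same)
  expect_equal(nrow(net2), 3)
  expect_true(all(net2$weight == 1))
})

test_that("load_disease_gene collapses duplicates and validates rows", {
  df <- data.frame(disease = c("d1", "d1", "d2"), gene = c("g1", "g1", "g2"),
                   regulation = c("over", "over", "under"))
  net <- load_disease_gene(df)
  expect_equal(nrow(net), 2)
  expect_true(all(net$weight == 1))
  expect_equal(sort(attr(net, "universe_a")), c("d1", "d2"))
  reg <- attr(net, "regulation")
  expect_equal(reg$regulation[reg$gene == "g2"], "under")

  expect_warning(empty <- load_disease_gene(data.frame(a = character(), b = character())),
                 "empty")
  expect_equal(nrow(empty), 0)
  expect_error(load_disease_gene(data.frame(a = c("d", ""), b = c("g", "h"))),
               "line 2")
})

test_that("within-layer networks are stored canonically and reject self-loops", {
  net <- assoc_net(tibble::tibble(from = c("b", "c"), to = c("a", "a"), weight = 1),
                   "GG", c("a", "b", "c"))
  expect_true(all(net$from < net$to))
  expect_error(
    assoc_net(tibble::tibble(from = "a", to = "a", weight = 1), "GG", "a"),
    "self-loops"
  )
  expect_error(
    assoc_net(tibble::tibble(from = "a", to = "zz", weight = 1), "GG", c("a", "b")),
    "universe"
  )
})

test_that("edge lists round-trip through TSV", {
  net <- toy_networks()$sg
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(net, path)
  back <- read_edges(path, "SG", attr(net, "universe_a"), attr(net, "universe_b"))
  expect_equal(as.data.frame(back), as.data.frame(net))
})
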