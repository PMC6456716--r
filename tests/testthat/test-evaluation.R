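test_that("make_folds partitions associations into near-equal folds", {
  dg <- random_bipartite_net(10, 30, 101, seed = 2)
  plan <- make_folds(dg, k = 10, rng_seed = 4)
  sizes <- as.vector(table(plan$fold))
  expect_equal(sum(sizes), 101)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sort(table(plan$fold) == 11), sort(c(rep(FALSE, 9), TRUE)),
               ignore_attr = TRUE)
  # partition covers exactly the edge set
  expect_equal(sort(paste(plan$from, plan$to)), sort(paste(dg$from, dg$to)))
  # determinism
  plan2 <- make_folds(dg, k = 10, rng_seed = 4)
  expect_identical(as.data.frame(plan), as.data.frame(plan2))
  expect_error(make_folds(dg, k = 1, rng_seed = 1), "at least 2")
})

test_that("roc_auc handles the canonical separable, inverted and tied cases", {
  r1 <- roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(r1$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1), c(0, 0, 1))$auc, 0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  # curve anchors
  expect_equal(r1$fpr[1], 0)
  expect_equal(r1$tpr[length(r1$tpr)], 1)
  expect_true(all(diff(r1$fpr) >= 0) && all(diff(r1$tpr) >= 0))
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("roc_auc equals brute-force Mann-Whitney counting with ties", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels)$auc, auc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, 0.5)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC symmetry: inverting labels flips the area", {
  set.seed(11)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.5)
  expect_equal(roc_auc(scores, labels)$auc, 1 - roc_auc(scores, 1 - labels)$auc)
})

test_that("fold removal is reversible and the random method is calibrated", {
  study <- simulate_study(synth_config(
    n_diseases = 12, n_genes = 60, n_sites = 120, n_conditions = 20,
    n_modules = 4, rng_seed = 7
  ))
  nets <- suppressWarnings(build_networks(study))
  plan <- make_folds(nets$dg, k = 5, rng_seed = 2)
  # removing then restoring the test fold reproduces the original edge set
  test1 <- plan[plan$fold == 1, ]
  kept <- !(paste(nets$dg$from, nets$dg$to) %in% paste(test1$from, test1$to))
  restored <- sort(c(paste(nets$dg$from, nets$dg$to)[kept],
                     paste(test1$from, test1$to)))
  expect_equal(restored, sort(paste(nets$dg$from, nets$dg$to)))

  cv <- cross_validate(nets, plan, methods = "random", rng_seed = 6)
  expect_gt(cv$overall$n_pairs, 2000)
  expect_gte(cv$overall$auc, 0.45)
  expect_lte(cv$overall$auc, 0.55)
})

test_that("perfectly informative scores give AUC 1 through the CV pooling", {
  scores <- tibble::tibble(label = rep(c(1, 0), each = 50),
                           score = c(runif(50, 0.6, 1), runif(50, 0, 0.4)))
  expect_equal(roc_auc(scores$score, scores$label)$auc, 1)
})

test_that("host-gene diagnostic recovers engineered self-correlation", {
  study <- small_study()
  expr <- build_expression_profile(study$gene_rpkm, study$replicate_map)
  # methylation copied from host-gene expression rows
  sites <- study$sites[1:30, ]
  vals <- expr$values[sites$host_gene, , drop = FALSE]
  rownames(vals) <- sites$site_id
  meth <- structure(list(ids = sites$site_id, conditions = expr$conditions,
                         values = vals, sites = sites),
                    class = c("meth_profile", "mw_profile"))
  diag <- host_gene_diagnostic(meth, expr, n_perm = 100, rng_seed = 1)
  expect_true(all(abs(diag$self$corr - 1) < 1e-12))
  expect_lt(abs(mean(diag$null)), 0.25)

  # independent methylation: self correlations indistinguishable from null
  set.seed(2)
  vals2 <- matrix(rnorm(length(vals)), nrow(vals), dimnames = dimnames(vals))
  meth2 <- structure(list(ids = sites$site_id, conditions = expr$conditions,
                          values = vals2, sites = sites),
                     class = c("meth_profile", "mw_profile"))
  diag2 <- host_gene_diagnostic(meth2, expr, n_perm = 200, rng_seed = 3)
  ks <- suppressWarnings(stats::ks.test(diag2$self$corr, as.vector(diag2$null)))
  expect_gt(ks$p.value, 0.01)

  # degenerate permutation count
  diag0 <- host_gene_diagnostic(meth, expr, n_perm = 0, rng_seed = 1)
  expect_equal(ncol(diag0$null), 0)
  expect_equal(nrow(diag0$self), 30)
})

test_that("glance and tidy summarise cross-validation results", {
  nets <- toy_networks()
  plan <- make_folds(nets$dg, k = 2, rng_seed = 3)
  cv <- cross_validate(nets, plan, methods = c("baseline", "random"),
                       rng_seed = 1)
  g <- glance(cv)
  expect_equal(sort(g$method), c("baseline", "random"))
  expect_true(all(g$auc >= 0 & g$auc <= 1))
  td <- tidy(cv)
  expect_true(all(c("method", "disease", "auc") %in% names(td)))
})
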