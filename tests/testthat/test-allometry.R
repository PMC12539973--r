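test_that("perfectly allometric shapes give R^2 = 1 and zero residuals", {
  tree <- default_two_clade_tree()
  set.seed(90)
  sizes <- setNames(exp(rnorm(16, log(100), 0.3)), tree$tip.label)
  slope <- rnorm(12)
  Y <- outer(log(sizes) - mean(log(sizes)), slope) +
    matrix(rep(rnorm(12), each = 16), 16)
  rownames(Y) <- tree$tip.label
  fit <- phylo_allometry_fit(Y, sizes, tree, lambda = 0, n_perm = 99, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_lt(fit$p_value, 0.05)
  # residual shapes collapse onto the mean shape
  res <- allometry_residuals(fit)
  expect_equal(res, matrix(colMeans(Y), 16, 12, byrow = TRUE,
                           dimnames = dimnames(Y)), tolerance = 1e-9)
})

test_that("lambda = 0 fit equals the normal-equations OLS oracle", {
  tree <- default_two_clade_tree()
  set.seed(91)
  sizes <- setNames(exp(rnorm(16, log(100), 0.3)), tree$tip.label)
  Y <- matrix(rnorm(16 * 10), 16, 10, dimnames = list(tree$tip.label, NULL))
  fit <- phylo_allometry_fit(Y, sizes, tree, lambda = 0, n_perm = 99, seed = 1)
  oracle <- oracle_ols_fit(Y, log(sizes))
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-10)
  expect_equal(unname(fit$residuals), unname(oracle$residuals), tolerance = 1e-10)
  # residuals orthogonal to the (transformed = identity-scaled) predictor
  xc <- log(sizes) - mean(log(sizes))
  expect_lt(max(abs(t(fit$residuals) %*% xc)), 1e-8)
})

test_that("lambda = 1 fit equals the brute-force GLS oracle on small trees", {
  set.seed(92)
  for (tree in oracle_test_trees()[c("four", "five", "six")]) {
    n <- length(tree$tip.label)
    sizes <- setNames(exp(rnorm(n, log(50), 0.4)), tree$tip.label)
    Y <- matrix(rnorm(n * 6), n, 6, dimnames = list(tree$tip.label, NULL))
    fit <- phylo_allometry_fit(Y, sizes, tree, lambda = 1, n_perm = 99, seed = 1)
    oracle <- oracle_pgls_fit(Y, log(sizes), ape::vcv(tree))
    expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-8)
    expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-8)
  }
})

test_that("zero-slope fits return the original shapes as residual shapes", {
  tree <- default_two_clade_tree()
  set.seed(93)
  sizes <- setNames(rep(100, 16), tree$tip.label) # constant size: slope irrelevant
  sizes <- sizes * exp(rnorm(16, 0, 0.2))
  Y <- matrix(rep(rnorm(8), each = 16), 16, 8, dimnames = list(tree$tip.label, NULL))
  Y <- Y + 0 # shapes constant across taxa: slope exactly 0
  fit <- phylo_allometry_fit(Y, sizes, tree, lambda = 0, n_perm = 99, seed = 1)
  expect_equal(unname(fit$beta["log_size", ]), rep(0, 8), tolerance = 1e-10)
  expect_equal(allometry_residuals(fit), Y, tolerance = 1e-10)
})

test_that("lambda is validated and non-zero lambda warns on residual extraction", {
  tree <- default_two_clade_tree()
  set.seed(94)
  sizes <- setNames(exp(rnorm(16, 4, 0.2)), tree$tip.label)
  Y <- matrix(rnorm(16 * 5), 16, 5, dimnames = list(tree$tip.label, NULL))
  expect_error(phylo_allometry_fit(Y, sizes, tree, lambda = 1.2),
               class = "shaperate_validation")
  fit1 <- phylo_allometry_fit(Y, sizes, tree, lambda = 1, n_perm = 99, seed = 1)
  expect_warning(allometry_residuals(fit1), "lambda")
})

test_that("corrected shapes feed the disparity and rate battery unchanged", {
  sim <- cached_fixture("allometric")
  run <- fixture_rate_run(sim, n_sims = 20, seed = 2)
  sizes <- shaperate:::species_mean_sizes(run$aligned)
  fit <- phylo_allometry_fit(run$shapes, sizes, run$tree, lambda = 0,
                             n_perm = 99, seed = 1)
  expect_gt(fit$r_squared, 0.05) # planted allometry is visible
  corrected <- allometry_residuals(fit)
  cl <- run$clade_map
  rep <- disparity_report(corrected[names(cl)[cl == "clade_a"], ],
                          corrected[names(cl)[cl == "clade_b"], ],
                          n_perm = 99, seed = 1)
  expect_true(all(c("pv_ratio", "pv_p", "distance_ratio", "distance_p") %in% names(rep)))
  cmp <- compare_rates_two_groups(run$tree, corrected, cl, focal = "clade_a",
                                  n_sims = 49, seed = 1)
  expect_gt(cmp$ratio, 0)
})
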