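make_univariate_model <- function(values) {
  # a 1-coordinate "shape" model via PCA of the tip values
  shape_pca(matrix(values, ncol = 1, dimnames = list(names(values), NULL)))
}

test_that("observed branch changes: constant states give zero, two-tip hand case", {
  tree <- read_time_tree(text = "(A:1,B:1);")
  m <- make_univariate_model(c(A = 0, B = 2))
  st <- bm_ancestral_states(tree, m$scores)
  obs <- observed_branch_changes(m, tree, st)
  expect_equal(obs$d_obs, c(1, 1)) # root estimate 1, tips 0 and 2
  # constant states
  stc <- st
  stc$states[] <- 0.7
  expect_equal(observed_branch_changes(m, tree, stc)$d_obs, c(0, 0))
})

test_that("distance in PC space equals distance in landmark space (isometry)", {
  set.seed(80)
  x <- matrix(rnorm(6 * 30), 6, 30, dimnames = list(paste0("t", 1:6), NULL))
  m <- shape_pca(x)
  tree <- oracle_test_trees()$six
  rownames(m$scores) <- tree$tip.label
  m$taxa <- tree$tip.label
  st <- bm_ancestral_states(tree, m$scores)
  obs <- observed_branch_changes(m, tree, st)
  et <- edge_table(tree)
  labs <- c(tree$tip.label, paste0("node_", 7:11))
  d_pc <- unname(sqrt(rowSums((st$states[labs[et$child], ] - st$states[labs[et$parent], ])^2)))
  expect_equal(obs$d_obs, d_pc, tolerance = 1e-10)
})

test_that("neutral expectation matches the half-normal closed form", {
  # one branch, one component, variance v = sigma2 * n_gen:
  # E|N(0,v)| = sqrt(2v/pi)
  tree <- read_time_tree(text = "(A:1,B:1);")
  gt <- rescale_to_generations(tree, c(A = 25, B = 25)) # 40,000 gens/branch
  m <- make_univariate_model(c(A = 0, B = 2))
  sigma2 <- 2.5e-5
  v <- sigma2 * 40000
  d <- simulate_neutral_expectation(m, gt, sigma2, root_scores = 0,
                                    n_sims = 20000, seed = 4, mode = "true_node")
  expect_equal(d$d_exp, rep(sqrt(2 * v / pi), 2), tolerance = 0.02)
})

test_that("neutral expectation is seed-deterministic and scales with branch length", {
  set.seed(81)
  x <- matrix(rnorm(8 * 20), 8, 20)
  tree <- ape::rcoal(8)
  rownames(x) <- tree$tip.label
  m <- shape_pca(x)
  gt <- rescale_to_generations(tree, setNames(rep(25, 8), tree$tip.label))
  s2 <- rep(1e-7, ncol(m$basis))
  d1 <- simulate_neutral_expectation(m, gt, s2, n_sims = 50, seed = 9)
  d2 <- simulate_neutral_expectation(m, gt, s2, n_sims = 50, seed = 9)
  expect_identical(d1, d2)
  d3 <- simulate_neutral_expectation(m, gt, s2, n_sims = 50, seed = 10)
  expect_false(identical(d1$d_exp, d3$d_exp))
})

test_that("longer branches have larger expected change", {
  set.seed(82)
  for (r in 1:20) {
    tree <- ape::rcoal(6)
    tree$edge.length <- tree$edge.length + 0.05
    x <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(tree$tip.label, NULL))
    m <- shape_pca(x)
    gt <- suppressWarnings(
      rescale_to_generations(tree, setNames(rep(25, 6), tree$tip.label))
    )
    s2 <- rep(1e-9, ncol(m$basis))
    d <- simulate_neutral_expectation(m, gt, s2, n_sims = 4000, seed = r)
    et <- gt$edges
    ord <- order(et$n_gen)
    # for clearly distinct branch lengths the expectation must increase
    len <- et$n_gen[ord]; de <- d$d_exp[ord]
    for (i in seq_len(length(ord) - 1)) {
      for (j in (i + 1):length(ord)) {
        if (len[j] > 1.5 * len[i]) expect_gt(de[j], de[i])
      }
    }
  }
})

test_that("Monte-Carlo error of the expectation halves when sims quadruple", {
  tree <- read_time_tree(text = "(A:1,B:1);")
  gt <- rescale_to_generations(tree, c(A = 25, B = 25))
  m <- make_univariate_model(c(A = 0, B = 2))
  sizes <- c(25, 50, 100, 200, 400)
  ses <- vapply(sizes, function(ns) {
    reps <- vapply(1:40, function(r) {
      simulate_neutral_expectation(m, gt, 1e-5, n_sims = ns,
                                   seed = 1000 * ns + r)$d_exp[1]
    }, numeric(1))
    stats::sd(reps)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(ses) ~ log(sizes)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("degenerate simulations are rejected", {
  tree <- read_time_tree(text = "(A:1,B:1);")
  gt <- rescale_to_generations(tree, c(A = 25, B = 25))
  m <- make_univariate_model(c(A = 0, B = 2))
  expect_error(simulate_neutral_expectation(m, gt, 0), class = "shaperate_degenerate_simulation")
  expect_error(simulate_neutral_expectation(m, gt, c(1e-5, 1e-5)),
               class = "shaperate_dimension")
})

test_that("excess table: unit ratios, classification, zero-expected error", {
  obs <- tibble::tibble(edge = 1:2, parent = 3, child = 1:2,
                        child_label = c("A", "B"), terminal = TRUE,
                        d_obs = c(2, 0.5))
  exp_t <- obs; names(exp_t)[6] <- "d_exp"; exp_t$d_exp <- c(2, 1)
  tab <- excess_change_table(obs, exp_t)
  expect_equal(tab$R, c(1, 0.5))
  expect_equal(tab$classification, c("expected", "stabilizing"))
  exp_t$d_exp <- c(0, 1)
  expect_error(excess_change_table(obs, exp_t), class = "shaperate_undefined_rate")
})

test_that("sigma2_mult on a star tree equals the divisor-n variance", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  set.seed(83)
  y <- matrix(rnorm(5 * 7), 5, 7, dimnames = list(star$tip.label, NULL))
  got <- sigma2_mult(star, y)
  want <- sum(sweep(y, 2, colMeans(y))^2) / 5
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(sigma2_mult(star, matrix(2, 5, 3, dimnames = list(star$tip.label, NULL))), 0)
})

test_that("sigma2_mult recovers the generating rate", {
  # 100 tips, 40 coordinates at rate 2 each: estimate close to 80
  set.seed(84)
  tree <- ape::rcoal(100)
  hits <- 0
  for (r in 1:10) {
    y <- simulate_bm_tips(tree, 40, rate = 2)
    ratio <- sigma2_mult(tree, y) / 80
    if (ratio >= 0.85 && ratio <= 1.15) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("two-group rate comparison recovers a planted 4x contrast", {
  tree <- default_two_clade_tree()
  cl <- default_clade_map(tree)
  clb <- assign_branch_clades(tree, cl)
  rate_by_edge <- ifelse(clb == "clade_a", 4, 1)
  set.seed(85)
  ratios <- c(); ps <- c()
  for (r in 1:20) {
    y <- simulate_bm_tips(tree, 40, rate_by_edge = rate_by_edge)
    cmp <- compare_rates_two_groups(tree, y, cl, focal = "clade_a",
                                    n_sims = 99, seed = r)
    ratios <- c(ratios, cmp$ratio); ps <- c(ps, cmp$p_value)
  }
  expect_gte(median(ratios), 3)
  expect_lte(median(ratios), 5)
  expect_gte(mean(ps < 0.05), 0.8)
})

test_that("two-group comparison is deterministic and validates groups", {
  tree <- default_two_clade_tree()
  set.seed(86)
  y <- simulate_bm_tips(tree, 10)
  cl <- default_clade_map(tree)
  a <- compare_rates_two_groups(tree, y, cl, focal = "clade_a", n_sims = 49, seed = 3)
  b <- compare_rates_two_groups(tree, y, cl, focal = "clade_a", n_sims = 49, seed = 3)
  expect_identical(a, b)
  perm <- compare_rates_two_groups(tree, y, cl, focal = "clade_a", n_sims = 49,
                                   seed = 3, method = "permutation")
  expect_equal(perm$ratio, a$ratio)
  bad <- setNames(c("x", rep("y", 15)), tree$tip.label)
  expect_error(compare_rates_two_groups(tree, y, bad), class = "shaperate_validation")
})

test_that("region rate comparison: identical regions give ratio 1, 3x region recovered", {
  tree <- default_two_clade_tree()
  set.seed(87)
  y <- simulate_bm_tips(tree, 20)
  same <- list(r1 = y, r2 = y, r3 = y)
  cmp <- compare_rates_regions(tree, same, n_sims = 49, seed = 1)
  expect_equal(cmp$ratio, 1, tolerance = 1e-12)
  expect_gt(cmp$p_value, 0.5)
  # one of four regions at triple rate
  ratios <- vapply(1:20, function(r) {
    regions <- c(lapply(1:3, function(i) simulate_bm_tips(tree, 15, rate = 1)),
                 list(simulate_bm_tips(tree, 15, rate = 3)))
    names(regions) <- paste0("reg", 1:4)
    compare_rates_regions(tree, regions, n_sims = 5, seed = r)$ratio
  }, numeric(1))
  expect_gte(median(ratios), 2.25)
  expect_lte(median(ratios), 3.75)
  # per-region rates are reported for every named region
  regions <- list(a = y, b = y * 2, c = y, d = y)
  out <- compare_rates_regions(tree, regions, n_sims = 9, seed = 1)
  expect_equal(out$rates$region, c("a", "b", "c", "d"))
  expect_error(compare_rates_regions(tree, list(a = y)), class = "shaperate_validation")
})

test_that("rate correlations: identical tables give r = 1 and match the formula oracle", {
  tree <- default_two_clade_tree()
  et <- edge_table(tree)
  cl <- assign_branch_clades(tree, default_clade_map(tree))
  set.seed(88)
  mk_table <- function(vals) {
    t <- et[, c("edge", "parent", "child", "child_label", "terminal")]
    t$clade <- cl; t$R <- vals
    class(t) <- c("branch_rate_table", class(t))
    t
  }
  v1 <- abs(rnorm(nrow(et), 1, 0.4))
  v2 <- abs(rnorm(nrow(et), 1, 0.4))
  rc <- rate_correlations(list(x = mk_table(v1), y = mk_table(v1)))
  expect_equal(rc$r[rc$stratum == "combined"], 1, tolerance = 1e-12)
  rc2 <- rate_correlations(list(x = mk_table(v1), y = mk_table(v2)))
  comb <- rc2[rc2$stratum == "combined", ]
  # direct covariance / sd oracle
  r_oracle <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(comb$r, r_oracle, tolerance = 1e-12)
  expect_setequal(unique(rc2$stratum), c("combined", "clade_a", "clade_b"))
  expect_equal(comb$n, nrow(et))
})

test_that("excess clade comparison uses mean rates and the exact Wilcoxon", {
  tree <- default_two_clade_tree()
  et <- edge_table(tree)
  cl <- assign_branch_clades(tree, default_clade_map(tree))
  t <- et[, c("edge", "parent", "child", "child_label", "terminal")]
  t$clade <- cl
  set.seed(89)
  t$R <- ifelse(cl == "clade_a", abs(rnorm(nrow(t), 2, 0.2)), abs(rnorm(nrow(t), 1, 0.2)))
  cmp <- excess_clade_comparison(t, "clade_a", "clade_b")
  expect_equal(cmp$excess_ratio,
               mean(t$R[cl == "clade_a"]) / mean(t$R[cl == "clade_b"]))
  expect_lt(cmp$p_value, 0.001)
})
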