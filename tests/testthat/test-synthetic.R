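test_that("template: default 1475 points in 4 named regions, exact partition, deterministic", {
  tp <- make_template()
  expect_equal(nrow(tp$template), 1475)
  expect_equal(unique(tp$regions$region), default_regions())
  expect_equal(nrow(tp$regions), 1475)
  tp2 <- make_template(40, c(a = 10, b = 10, c = 10, d = 10))
  expect_equal(nrow(tp2$template), 40)
  expect_equal(as.vector(table(tp2$regions$region)[c("a", "b", "c", "d")]),
               rep(10L, 4))
  expect_identical(make_template(40, c(a = 10, b = 10, c = 10, d = 10)), tp2)
  expect_equal(centroid_size(tp2$template), 1, tolerance = 1e-12)
  expect_error(make_template(40, c(a = 10, b = 10)), class = "shaperate_validation")
  expect_error(make_template(12, c(a = 3, b = 3, c = 3, d = 3)),
               class = "shaperate_validation")
})

test_that("default tree has the two-clade 7+9 design and is ultrametric", {
  tree <- default_two_clade_tree(20)
  expect_equal(ape::Ntip(tree), 16)
  cl <- default_clade_map(tree)
  expect_equal(sum(cl == "clade_a"), 7)
  expect_equal(sum(cl == "clade_b"), 9)
  expect_true(ape::is.ultrametric(tree, tol = 1e-8))
  expect_true(ape::is.binary(tree))
  expect_equal(max(ape::node.depth.edgelength(tree)), 20)
})

test_that("noise-free single-specimen scenarios reproduce species means exactly", {
  sc <- synthetic_scenario(noise_sd = 0, dimorphism = 0, n_per_species = 2,
                           size_sigma2 = 0, seed = 11)
  sim <- simulate_shape_evolution(sc)
  # specimens are rigid transforms of the species mean shapes: after
  # removing size/rotation/translation the distance must be ~0
  sp <- "a3"
  ids <- which(sim$dataset$specimens$species == sp)
  cfg <- sim$dataset$coords[, , ids[1]]
  cfg <- shaperate:::center_config(cfg)
  cfg <- cfg / sqrt(sum(cfg^2))
  truth_cfg <- matrix(sim$truth$species_mean_shapes[sp, ], ncol = 3, byrow = TRUE)
  truth_cfg <- shaperate:::center_config(truth_cfg)
  truth_cfg <- truth_cfg / sqrt(sum(truth_cfg^2))
  rot <- shaperate:::optimal_rotation(cfg, truth_cfg)
  expect_lt(procrustes_distance(cfg %*% rot, truth_cfg), 1e-8)
})

test_that("simulation is bit-identical under the same scenario and seed", {
  a <- simulate_shape_evolution(make_fixture_scenario("null", seed = 5))
  b <- simulate_shape_evolution(make_fixture_scenario("null", seed = 5))
  expect_identical(a$dataset$coords, b$dataset$coords)
  expect_identical(a$truth$node_coords, b$truth$node_coords)
  c <- simulate_shape_evolution(make_fixture_scenario("null", seed = 6))
  expect_false(identical(a$dataset$coords, c$dataset$coords))
})

test_that("fixture scenarios mark their planted structure", {
  null_sc <- make_fixture_scenario("null")
  expect_null(null_sc$kappa)
  expect_equal(null_sc$dimorphism, 0)
  expect_equal(null_sc$allometry_slope, 0)
  ofb <- make_fixture_scenario("one_fast_branch")
  expect_equal(ofb$kappa, c(a1 = 9))
  fc <- make_fixture_scenario("fast_clade")
  expect_equal(unname(fc$kappa), rep(4, 13)) # 7 tips + 6 internal incl. stem
  tree <- default_two_clade_tree()
  cl <- assign_branch_clades(tree, default_clade_map(tree))
  expect_setequal(names(fc$kappa), edge_table(tree)$child_label[cl == "clade_a"])
  sim <- cached_fixture("one_fast_branch")
  expect_equal(unname(sim$truth$kappa[["a1"]]), 9)
  expect_true(all(sim$truth$kappa[names(sim$truth$kappa) != "a1"] == 1))
  expect_error(make_fixture_scenario("bogus"), class = "shaperate_validation")
})

test_that("planted dimorphism appears between male and female consensus shapes", {
  sim <- cached_fixture("dimorphic")
  al <- gpa_align(sim$dataset)
  cons <- consensus_by_species_sex(al)
  sc <- sim$truth$scenario
  gaps <- vapply(unique(cons$species), function(sp) {
    m <- cons$shape[[which(cons$species == sp & cons$sex == "male")]]
    f <- cons$shape[[which(cons$species == sp & cons$sex == "female")]]
    procrustes_distance(m, f)
  }, numeric(1))
  # offset magnitude ~ dimorphism (0.05) against consensus noise
  expect_gt(median(gaps), 0.5 * sc$dimorphism)
  expect_lt(median(gaps), 2 * sc$dimorphism)
  # and the null fixture shows much smaller sex gaps
  sim0 <- cached_fixture("null")
  cons0 <- consensus_by_species_sex(gpa_align(sim0$dataset))
  gaps0 <- vapply(unique(cons0$species), function(sp) {
    m <- cons0$shape[[which(cons0$species == sp & cons0$sex == "male")]]
    f <- cons0$shape[[which(cons0$species == sp & cons0$sex == "female")]]
    procrustes_distance(m, f)
  }, numeric(1))
  expect_gt(median(gaps), 1.5 * median(gaps0))
})

test_that("tip disparity grows linearly with root depth under constant rates", {
  depths <- c(5, 10, 20, 40)
  set.seed(95)
  pv <- vapply(depths, function(d) {
    vals <- vapply(1:3, function(r) {
      sc <- synthetic_scenario(tree = default_two_clade_tree(d),
                               noise_sd = 0, dimorphism = 0,
                               n_per_species = 2, seed = 100 * d + r)
      sim <- simulate_shape_evolution(sc)
      procrustes_variance(sim$truth$species_mean_shapes)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  fit <- stats::lm(pv ~ depths)
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.8)
})

test_that("scenario validation catches impossible settings", {
  expect_error(synthetic_scenario(n_basis = 300, template_k = 60),
               class = "shaperate_validation")
  expect_error(synthetic_scenario(n_per_species = 3), class = "shaperate_validation")
  expect_error(synthetic_scenario(kappa = c(zz = 2)), class = "shaperate_validation")
  expect_error(synthetic_scenario(kappa = c(a1 = -1)), class = "shaperate_validation")
})

test_that("scenario files round trip through the standard loaders", {
  dir <- withr::local_tempdir()
  sim <- cached_fixture("null")
  paths <- write_scenario_files(sim, dir)
  back <- load_landmark_dataset(paths[["landmarks"]], "csv",
                                paths[["metadata"]], paths[["regions"]])
  expect_equal(back$coords, sim$dataset$coords, tolerance = 1e-6)
  tree <- read_time_tree(paths[["tree"]])
  expect_setequal(tree$tip.label, sim$truth$tree$tip.label)
  g <- read_generation_table(paths[["generations"]])
  expect_equal(g, sim$truth$gen_tree$generation_times)
  gt <- jsonlite::read_json(paths[["ground_truth"]])
  expect_equal(gt$kappa$a1, 1)
})
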