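# shared fixtures, built in code and cached for the session

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_shape_evolution(make_fixture_scenario(name, seed = seed))
  }
  .fixture_cache[[key]]
}

# tiny deterministic 3-specimen, 5-point dataset
tiny_dataset <- function() {
  set.seed(42)
  base <- matrix(rnorm(15), 5, 3)
  configs <- list(
    s1 = base,
    s2 = base + matrix(rnorm(15, sd = 0.05), 5, 3),
    s3 = base + matrix(rnorm(15, sd = 0.05), 5, 3)
  )
  meta <- tibble::tibble(
    specimen = c("s1", "s2", "s3"),
    species = c("sp1", "sp1", "sp2"),
    sex = c("male", "female", "male"),
    subspecies = NA_character_
  )
  regions <- tibble::tibble(point_index = 1:5,
                            region = c("r1", "r1", "r2", "r2", "r2"))
  landmark_dataset(configs, meta, regions)
}

# run the per-sex consensus -> rates pipeline on one simulated fixture;
# returns the branch rate table plus intermediates
fixture_rate_run <- function(sim, sex = "male", n_sims = 100L, seed = 1L,
                             mode = "reestimated", estimator = "mvbm") {
  ds <- sim$dataset
  ds <- landmark_dataset(ds$coords[, , ds$specimens$sex == sex, drop = FALSE],
                         ds$specimens[ds$specimens$sex == sex, ], ds$regions)
  aligned <- gpa_align(ds)
  shapes <- consensus_matrix(consensus_by_species_sex(aligned), sex)
  model <- shape_pca(shapes)
  tree <- sim$truth$tree
  gen <- sim$truth$gen_tree
  states <- if (estimator == "mvbm") mvbm_ancestral_states(tree, model$scores)
            else bm_ancestral_states(tree, model$scores)
  s2 <- per_generation_variance(gen, model$scores)
  root_label <- paste0("node_", length(tree$tip.label) + 1L)
  d_exp <- simulate_neutral_expectation(model, gen, s2,
                                        root_scores = states$states[root_label, ],
                                        n_sims = n_sims, seed = seed, mode = mode)
  d_obs <- observed_branch_changes(model, tree, states, tip_shapes = shapes)
  clades <- assign_branch_clades(tree, sim$truth$clade_map)
  list(rates = excess_change_table(d_obs, d_exp, clades = clades),
       shapes = shapes, model = model, states = states, aligned = aligned,
       tree = tree, gen = gen, sigma2 = s2, clade_map = sim$truth$clade_map)
}

# simulate BM tip data directly on a tree (independent of the package
# machinery): per-trait preorder accumulation of Gaussian increments
simulate_bm_tips <- function(tree, p, rate = 1, rate_by_edge = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  vals <- matrix(0, n_node, p)
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    r_e <- if (is.null(rate_by_edge)) rate else rate_by_edge[e]
    vals[ch, ] <- vals[par, ] + rnorm(p, sd = sqrt(r_e * tree$edge.length[e]))
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

flatten_config_test <- function(x) as.vector(t(x))
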