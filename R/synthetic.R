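#' Deterministic landmark template
#'
#' Builds a quasi-uniform point template on a hemisphere-plus-face-like
#' surface (a spherical Fibonacci lattice whose lower bands are projected
#' forward to mimic a facial block), centered with unit centroid size, and
#' partitions it contiguously (from the cranial vault downwards) into the
#' named regions. The construction is purely arithmetic: the same arguments
#' always give the bit-identical template.
#'
#' @param k total point count (default 1475)
#' @param regions named integer vector of per-region point counts summing to
#'   `k` (default: the four craniofacial regions, sizes split roughly
#'   proportionally)
#' @return list with `template` (`k x 3` matrix) and `regions` (tibble
#'   `point_index`, `region`)
#' @export
make_template <- function(k = 1475L, regions = NULL) {
  k <- as.integer(k)
  if (is.null(regions)) {
    nms <- default_regions()
    base <- k %/% 4L
    sizes <- rep(base, 4L)
    extra <- k - 4L * base
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    regions <- setNames(sizes, nms)
  }
  if (sum(regions) != k) {
    abort(sprintf("region sizes sum to %d but k = %d", sum(regions), k),
          class = "shaperate_validation")
  }
  if (any(regions < 4)) abort("every region needs >= 4 points", class = "shaperate_validation")

  i <- seq_len(k)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i - 0.5) / k
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * i
  pts <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  # points are ordered top (vault) to bottom; pull the lower bands forward
  # into a facial block
  face <- pts[, "z"] < 0
  pts[face, "y"] <- pts[face, "y"] + 0.55 * (-pts[face, "z"])
  pts[face, "z"] <- pts[face, "z"] * 0.8
  pts <- center_config(pts)
  pts <- pts / sqrt(sum(pts^2))
  tibble_regions <- tibble::tibble(
    point_index = i,
    region = rep(names(regions), times = regions)
  )
  list(template = pts, regions = tibble_regions)
}

#' Default two-clade time tree
#'
#' A 16-tip ultrametric binary phylogeny with two sister clades of 7
#' (`a1..a7`) and 9 (`b1..b9`) tips, mirroring the sampling design of a
#' diverse focal clade against a rapidly radiated, shallow reference clade:
#' the 7-tip clade's crown spans 80% of root depth, the 9-tip clade's only
#' 35%. Node ages are fixed fractions of `root_depth` (in Ma).
#'
#' @param root_depth root age in Ma (default 20)
#' @return an [ape::phylo] tree
#' @export
default_two_clade_tree <- function(root_depth = 20) {
  txt <- paste0(
    "(((a1:0.2,a2:0.2):0.6,((a3:0.15,a4:0.15):0.35,((a5:0.12,a6:0.12):0.23,",
    "a7:0.35):0.15):0.3):0.2,(b1:0.35,((b2:0.15,(b3:0.12,(b4:0.08,b5:0.08):0.04)",
    ":0.03):0.17,((b6:0.12,b7:0.12):0.18,(b8:0.1,b9:0.1):0.2):0.02):0.03):0.65);"
  )
  tree <- ape::read.tree(text = txt)
  tree$edge.length <- tree$edge.length * root_depth
  tree
}

#' Clade map for the default synthetic tree
#' @param tree a tree whose `a*` tips belong to the focal clade
#' @return named character vector tip -> `clade_a`/`clade_b`
#' @export
default_clade_map <- function(tree = default_two_clade_tree()) {
  setNames(ifelse(startsWith(tree$tip.label, "a"), "clade_a", "clade_b"),
           tree$tip.label)
}

#' Synthetic evolution scenario
#'
#' Fully specifies a generative run of [simulate_shape_evolution()]: the
#' time tree, per-branch rate multipliers, the per-generation shape
#' variance scale, generation times, shape-basis dimensionality, sexual
#' dimorphism offset, allometric coupling, within-species specimen noise,
#' specimens per species, the template size, and the seed.
#'
#' @param tree time tree (default [default_two_clade_tree()])
#' @param kappa named numeric vector of per-branch variance multipliers
#'   (names = branch child labels, see [edge_table()]); branches not named
#'   get 1
#' @param sigma2_base per-generation variance of each shape-basis dimension
#' @param generation_times named vector of tip generation times in years
#'   (default 25 for every tip)
#' @param n_basis number of orthonormal shape-variation directions
#' @param dimorphism Procrustes-scale male-female consensus offset
#' @param allometry_slope shape displacement per unit log centroid size
#' @param noise_sd per-coordinate within-species specimen noise SD
#' @param size_sigma2 per-generation variance of log centroid size
#' @param n_per_species specimens per species (even; half per sex)
#' @param template_k template point count for the scenario
#' @param region_sizes named per-region point counts (default: even split)
#' @param base_log_size root log centroid size (raw units)
#' @param seed integer seed
#' @return list of class `synthetic_scenario`
#' @export
synthetic_scenario <- function(tree = default_two_clade_tree(),
                               kappa = NULL,
                               sigma2_base = 3e-10,
                               generation_times = NULL,
                               n_basis = 40L,
                               dimorphism = 0.03,
                               allometry_slope = 0,
                               noise_sd = 0.002,
                               size_sigma2 = 3e-8,
                               n_per_species = 4L,
                               template_k = 60L,
                               region_sizes = NULL,
                               base_log_size = log(100),
                               seed = 1L) {
  validate_time_tree(tree)
  if (is.null(generation_times)) {
    generation_times <- setNames(rep(25, length(tree$tip.label)), tree$tip.label)
  }
  if (!is.null(kappa)) {
    if (any(kappa <= 0)) abort("kappa multipliers must be positive", class = "shaperate_validation")
    labs <- edge_table(tree)$child_label
    bad <- setdiff(names(kappa), labs)
    if (length(bad)) abort(paste0("kappa names are not branch labels: ", paste(bad, collapse = ", ")),
                           class = "shaperate_validation")
  }
  for (v in c(sigma2_base, dimorphism, noise_sd, size_sigma2)) {
    if (v < 0) abort("scales must be nonnegative", class = "shaperate_validation")
  }
  if (n_per_species %% 2 != 0 || n_per_species < 2) {
    abort("n_per_species must be even and >= 2 (half per sex)", class = "shaperate_validation")
  }
  if (n_basis > 3 * template_k - 7) {
    abort(sprintf("n_basis = %d exceeds the shape degrees of freedom 3k - 7 = %d",
                  n_basis, 3 * template_k - 7), class = "shaperate_validation")
  }
  structure(
    list(tree = tree, kappa = kappa, sigma2_base = sigma2_base,
         generation_times = generation_times, n_basis = as.integer(n_basis),
         dimorphism = dimorphism, allometry_slope = allometry_slope,
         noise_sd = noise_sd, size_sigma2 = size_sigma2,
         n_per_species = as.integer(n_per_species),
         template_k = as.integer(template_k), region_sizes = region_sizes,
         base_log_size = base_log_size, seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' Named fixture scenarios
#'
#' Fully specified, seeded scenarios used by the test-suite and
#' documentation: `"null"` (constant rate, no dimorphism, no allometry),
#' `"one_fast_branch"` (variance multiplier 9 on the terminal branch of tip
#' `a1`, the "human-like" branch of the 7-tip clade), `"fast_clade"`
#' (multiplier 4 on every branch of the 7-tip clade including its stem),
#' `"dimorphic"` and `"allometric"`. Fixtures use a 60-point template, a
#' 40-dimensional shape basis and a uniform 25-year generation time, so
#' planted per-generation rate contrasts translate directly into time-tree
#' rate contrasts.
#'
#' @param name one of `"null"`, `"one_fast_branch"`, `"fast_clade"`,
#'   `"dimorphic"`, `"allometric"`
#' @param seed integer seed
#' @return a [synthetic_scenario()]
#' @export
make_fixture_scenario <- function(name = c("null", "one_fast_branch", "fast_clade",
                                           "dimorphic", "allometric"),
                                  seed = 1L) {
  if (!is.character(name) || !name[1] %in% c("null", "one_fast_branch", "fast_clade",
                                             "dimorphic", "allometric")) {
    abort(sprintf("unknown fixture scenario '%s'", as.character(name)[1]),
          class = "shaperate_validation")
  }
  name <- match.arg(name)
  tree <- default_two_clade_tree()
  kappa <- switch(name,
    one_fast_branch = c(a1 = 9),
    fast_clade = {
      cl <- assign_branch_clades(tree, default_clade_map(tree))
      et <- edge_table(tree)
      setNames(rep(4, sum(cl == "clade_a")), et$child_label[cl == "clade_a"])
    },
    NULL
  )
  synthetic_scenario(
    tree = tree,
    kappa = kappa,
    dimorphism = if (name == "dimorphic") 0.05 else 0,
    allometry_slope = if (name == "allometric") 0.5 else 0,
    seed = seed
  )
}

# random proper rotation matrix (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Simulate shape evolution on a phylogeny
#'
#' Generates a landmark dataset under the generative model the rate
#' pipeline assumes: species mean shapes evolve by Brownian motion along
#' `n_basis` fixed orthonormal shape directions (constructed orthogonal to
#' the template's similarity transformations, so Procrustes superimposition
#' cannot remove the simulated signal), with per-branch variance
#' `sigma2_base * kappa_b * n_gen(b)`. Log centroid size evolves by BM with
#' optional allometric coupling into shape. Specimens are the species mean
#' plus a fixed sex offset (+/- dimorphism/2) plus isotropic coordinate
#' noise, then scaled to raw size and given a random rotation and
#' translation. Deterministic given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()]
#' @return list with `dataset` (a [landmark_dataset()]) and `truth` (tree,
#'   generation tree, per-branch kappa, basis, template, per-node basis
#'   coordinates and log sizes, species mean shapes, clade map, scenario)
#' @export
simulate_shape_evolution <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  k <- scenario$template_k
  p <- 3L * k
  tmpl <- make_template(k, scenario$region_sizes)
  template_flat <- flatten_config(tmpl$template)

  # similarity-transform directions at the template: 3 translations,
  # 3 infinitesimal rotations, 1 scaling
  xyz <- tmpl$template
  sim_dirs <- cbind(
    flatten_config(cbind(1, 0, 0)[rep(1, k), ]),
    flatten_config(cbind(0, 1, 0)[rep(1, k), ]),
    flatten_config(cbind(0, 0, 1)[rep(1, k), ]),
    flatten_config(cbind(-xyz[, 2], xyz[, 1], 0)),
    flatten_config(cbind(0, -xyz[, 3], xyz[, 2])),
    flatten_config(cbind(xyz[, 3], 0, -xyz[, 1])),
    template_flat
  )
  raw <- matrix(rnorm(p * (scenario$n_basis + 2L)), p)
  q <- qr.Q(qr(cbind(sim_dirs, raw)))
  basis <- q[, 8:(7 + scenario$n_basis), drop = FALSE]
  sex_dir <- q[, 8 + scenario$n_basis]
  allo_dir <- q[, 9 + scenario$n_basis]

  tree <- scenario$tree
  gen <- rescale_to_generations(tree, scenario$generation_times)
  et <- gen$edges
  kappa <- setNames(rep(1, nrow(et)), et$child_label)
  if (!is.null(scenario$kappa)) kappa[names(scenario$kappa)] <- scenario$kappa

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  u <- matrix(0, n_node, scenario$n_basis)
  lcs <- rep(scenario$base_log_size, n_node)
  preorder <- rev(ape::postorder(tree))
  for (e in preorder) {
    par <- et$parent[e]; ch <- et$child[e]
    sd_b <- sqrt(scenario$sigma2_base * kappa[e] * et$n_gen[e])
    u[ch, ] <- u[par, ] + rnorm(scenario$n_basis, sd = sd_b)
    lcs[ch] <- lcs[par] + rnorm(1, sd = sqrt(scenario$size_sigma2 * et$n_gen[e]))
  }
  rownames(u) <- names(lcs) <- node_labels(tree)

  species_means <- t(vapply(seq_len(n_tip), function(i) {
    template_flat + as.vector(basis %*% u[i, ]) +
      scenario$allometry_slope * (lcs[i] - scenario$base_log_size) * allo_dir
  }, numeric(p)))
  rownames(species_means) <- tree$tip.label

  n_half <- scenario$n_per_species %/% 2L
  configs <- list()
  meta <- list()
  for (i in seq_len(n_tip)) {
    sp <- tree$tip.label[i]
    for (sex in c("male", "female")) {
      offset <- (if (sex == "male") 0.5 else -0.5) * scenario$dimorphism * sex_dir
      for (rep_i in seq_len(n_half)) {
        id <- sprintf("%s_%s%d", sp, substr(sex, 1, 1), rep_i)
        flat <- species_means[i, ] + offset + rnorm(p, sd = scenario$noise_sd)
        cfg <- unflatten_config(flat) * exp(lcs[i])
        cfg <- cfg %*% random_rotation()
        cfg <- sweep(cfg, 2, rnorm(3, sd = exp(lcs[i])), `+`)
        configs[[id]] <- cfg
        meta[[id]] <- tibble::tibble(specimen = id, species = sp, sex = sex,
                                     subspecies = NA_character_)
      }
    }
  }
  dataset <- landmark_dataset(configs, dplyr::bind_rows(meta), tmpl$regions)
  truth <- list(
    tree = tree, gen_tree = gen,
    kappa = kappa,
    basis = basis, template = tmpl$template, sex_dir = sex_dir, allo_dir = allo_dir,
    node_coords = u, log_sizes = lcs,
    species_mean_shapes = species_means,
    clade_map = if (all(grepl("^[ab]", tree$tip.label))) default_clade_map(tree) else NULL,
    scenario = scenario
  )
  list(dataset = dataset, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the CSV dialects the loaders read (landmarks, metadata, region
#' map), the tree as newick, the generation-time table, and the ground
#' truth (per-branch kappa, per-node basis coordinates and log sizes) as
#' JSON.
#'
#' @param sim output of [simulate_shape_evolution()]
#' @param dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_scenario_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    landmarks = file.path(dir, "landmarks.csv"),
    metadata = file.path(dir, "metadata.csv"),
    regions = file.path(dir, "regions.csv"),
    tree = file.path(dir, "tree.nwk"),
    generations = file.path(dir, "generation_times.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_landmarks_csv(sim$dataset, paths["landmarks"], paths["metadata"], paths["regions"])
  ape::write.tree(sim$truth$tree, paths["tree"])
  gt <- sim$truth$gen_tree$generation_times
  utils::write.csv(data.frame(species = names(gt), generation_time_years = unname(gt)),
                   paths["generations"], row.names = FALSE)
  truth_json <- list(
    kappa = as.list(sim$truth$kappa),
    log_sizes = as.list(sim$truth$log_sizes),
    node_coords = apply(sim$truth$node_coords, 1, identity, simplify = FALSE),
    seed = sim$truth$scenario$seed
  )
  jsonlite::write_json(truth_json, paths["ground_truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
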