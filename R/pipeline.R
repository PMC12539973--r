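#' Analysis configuration
#'
#' Collects and validates everything [run_full_analysis()] needs. Inputs
#' may be in-memory objects or file paths (landmark CSV/TPS dialects,
#' newick, generation CSV). Separate deterministic random substreams are
#' derived from `seed` for each resampling stage, so results do not depend
#' on stage order.
#'
#' @param dataset a [landmark_dataset()], or a named list of paths
#'   (`landmarks`, `metadata`, optionally `regions`, `format`)
#' @param tree an [ape::phylo] time tree or newick path
#' @param generation_times named vector (years), tibble, or CSV path
#' @param clades named character vector species -> clade (exactly two
#'   clades partitioning the species), or a data frame `species,clade`
#' @param focal focal clade label (ratios are focal/reference)
#' @param seed integer master seed
#' @param n_sims simulations for the neutral expectation (default 100)
#' @param n_perm resampling count for significance tests (default 999)
#' @param mode expectation mode, `"true_node"` or `"reestimated"`
#' @param estimator ancestral estimator for observed data: `"mvbm"`
#'   (default) or `"bm"`
#' @param region_realign re-superimpose each region independently (default
#'   `TRUE`); `FALSE` reuses the whole-configuration alignment subset
#' @param allometry fit lambda-fixed allometry models (default `TRUE`)
#' @param allometry_lambdas lambda values to fit (default `c(0, 1)`)
#' @param allometry_corrected_rerun rerun disparity and rates on
#'   lambda = 0 allometry-corrected residuals (default `FALSE`)
#' @param sexes sexes to analyse (default both)
#' @return validated config list of class `shaperate_config`
#' @export
analysis_config <- function(dataset, tree, generation_times, clades, focal = NULL,
                            seed = 1L, n_sims = 100L, n_perm = 999L,
                            mode = c("true_node", "reestimated"),
                            estimator = c("mvbm", "bm"),
                            region_realign = TRUE,
                            allometry = TRUE,
                            allometry_lambdas = c(0, 1),
                            allometry_corrected_rerun = FALSE,
                            sexes = c("male", "female")) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  if (is.character(tree)) tree <- read_time_tree(tree)
  validate_time_tree(tree)
  if (!inherits(dataset, "landmark_dataset")) {
    if (!is.list(dataset) || is.null(dataset$landmarks) || is.null(dataset$metadata)) {
      abort("dataset must be a landmark_dataset or a list of paths (landmarks, metadata, [regions])",
            class = "shaperate_validation")
    }
    dataset <- load_landmark_dataset(dataset$landmarks, dataset$format %||% "csv",
                                     dataset$metadata, dataset$regions)
  }
  if (missing(generation_times) || is.null(generation_times)) {
    abort("a generation-time table is required", class = "shaperate_validation")
  }
  if (is.character(generation_times)) generation_times <- read_generation_table(generation_times)
  if (is.data.frame(generation_times)) {
    generation_times <- setNames(as.numeric(generation_times$generation_time_years),
                                 generation_times$species)
  }
  species <- sort(unique(dataset$specimens$species))
  if (!setequal(species, tree$tip.label)) {
    abort("dataset species and tree tips differ", class = "shaperate_validation")
  }
  missing_g <- setdiff(tree$tip.label, names(generation_times))
  if (length(missing_g)) {
    abort(paste0("generation times missing for: ", paste(missing_g, collapse = ", ")),
          class = "shaperate_validation")
  }
  if (is.data.frame(clades)) clades <- setNames(clades$clade, clades$species)
  if (!setequal(names(clades), species)) {
    abort("clade assignment does not partition the species set", class = "shaperate_validation")
  }
  clade_names <- sort(unique(unname(clades)))
  if (length(clade_names) != 2) {
    abort("exactly two clades are required", class = "shaperate_validation")
  }
  focal <- focal %||% clade_names[1]
  if (!focal %in% clade_names) abort("focal clade not found in assignment",
                                     class = "shaperate_validation")
  structure(
    list(dataset = dataset, tree = tree, generation_times = generation_times,
         clades = clades, focal = focal, reference = setdiff(clade_names, focal),
         seed = as.integer(seed), n_sims = as.integer(n_sims),
         n_perm = as.integer(n_perm), mode = mode, estimator = estimator,
         region_realign = isTRUE(region_realign),
         allometry = isTRUE(allometry), allometry_lambdas = allometry_lambdas,
         allometry_corrected_rerun = isTRUE(allometry_corrected_rerun),
         sexes = sexes),
    class = "shaperate_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with keys matching [analysis_config()] arguments;
#'   file-path entries are resolved relative to the YAML file's directory.
#' @return a `shaperate_config`
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.character(p) && !file.exists(p)) file.path(base, p) else p
  if (is.list(y$dataset)) y$dataset <- lapply(y$dataset, rel)
  y$tree <- rel(y$tree)
  y$generation_times <- rel(y$generation_times)
  if (is.list(y$clades)) y$clades <- unlist(y$clades)
  do.call(analysis_config, y)
}

subset_specimens <- function(dataset, keep) {
  landmark_dataset(dataset$coords[, , keep, drop = FALSE],
                   dataset$specimens[keep, , drop = FALSE],
                   dataset$regions)
}

# consensus centroid sizes: mean specimen centroid size per species
species_mean_sizes <- function(aligned) {
  df <- tibble::tibble(size = aligned$centroid_sizes,
                       species = aligned$specimens$species)
  out <- dplyr::summarise(dplyr::group_by(df, species), size = mean(size), .groups = "drop")
  setNames(out$size, out$species)
}

# one region x sex analysis cell
analyze_region_sex <- function(shapes, sizes, config, region, sex, gen) {
  tree <- config$tree
  clade_map <- config$clades
  focal <- config$focal; reference <- config$reference
  seed0 <- config$seed

  model <- shape_pca(shapes)
  states <- if (config$estimator == "mvbm") {
    mvbm_ancestral_states(tree, model$scores)
  } else {
    bm_ancestral_states(tree, model$scores)
  }
  sigma2_pc <- per_generation_variance(gen, model$scores)
  root_label <- paste0("node_", length(tree$tip.label) + 1L)
  d_exp <- simulate_neutral_expectation(
    model, gen, sigma2_pc,
    root_scores = states$states[root_label, ],
    n_sims = config$n_sims,
    seed = derive_seed(seed0, stage_ids[["expectation"]] + region_stage_offset(region, sex)),
    mode = config$mode,
    estimator = config$estimator
  )
  d_obs <- observed_branch_changes(model, tree, states, tip_shapes = shapes)
  branch_clades <- assign_branch_clades(tree, clade_map)
  rates <- excess_change_table(d_obs, d_exp, clades = branch_clades)

  disparity <- disparity_report(
    shapes[names(clade_map)[clade_map == focal], , drop = FALSE],
    shapes[names(clade_map)[clade_map == reference], , drop = FALSE],
    n_perm = config$n_perm,
    seed = derive_seed(seed0, stage_ids[["disparity"]] + region_stage_offset(region, sex))
  )
  excess_cmp <- excess_clade_comparison(rates, focal, reference)
  bm_cmp <- compare_rates_two_groups(
    tree, shapes, clade_map, focal = focal,
    n_sims = config$n_perm,
    seed = derive_seed(seed0, stage_ids[["rates_groups"]] + region_stage_offset(region, sex))
  )
  allometry <- if (config$allometry) {
    purrr::map_dfr(config$allometry_lambdas, function(lam) {
      fit <- phylo_allometry_fit(
        shapes, sizes, tree, lambda = lam, n_perm = config$n_perm,
        seed = derive_seed(seed0, stage_ids[["allometry"]] + region_stage_offset(region, sex))
      )
      tibble::tibble(region = region, sex = sex, lambda = lam,
                     r_squared = fit$r_squared, p_value = fit$p_value)
    })
  } else {
    tibble::tibble(region = character(), sex = character(), lambda = numeric(),
                   r_squared = numeric(), p_value = numeric())
  }
  list(model = model, states = states, sigma2_pc = sigma2_pc, rates = rates,
       disparity = disparity, excess_cmp = excess_cmp, bm_cmp = bm_cmp,
       allometry = allometry, shapes = shapes, sizes = sizes)
}

region_stage_offset <- function(region, sex) {
  # small deterministic offset so each region x sex cell has its own stream
  100L * (sum(utf8ToInt(region)) %% 97L) + 10000L * (sex == "female")
}

#' Run the full analysis battery
#'
#' Executes, separately for each sex: Procrustes superimposition of the
#' whole configuration and of each anatomical region (regions re-aligned
#' independently by default), species consensus shapes, PCA, ancestral
#' state estimation (mvBM by default), generation rescaling, the simulated
#' neutral expectation, branch-specific excess-change rates, the disparity
#' battery, multivariate rate comparisons between clades and across
#' regions, rate correlations, and lambda-fixed allometry fits. The whole
#' configuration is treated as a fifth "region" named `"whole"` for
#' uniform reporting.
#'
#' @param config a [analysis_config()] (or a YAML path)
#' @return object of class `analysis_report`
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "shaperate_config"))
  dataset <- config$dataset
  region_names <- unique(dataset$regions$region)
  multi_region <- length(region_names) > 1
  all_regions <- c("whole", if (multi_region) region_names)
  gen <- rescale_to_generations(config$tree, config$generation_times)

  per_sex <- list()
  for (sex in config$sexes) {
    keep <- dataset$specimens$sex == sex
    if (!any(keep)) abort(sprintf("no specimens for sex '%s'", sex),
                          class = "shaperate_validation")
    ds_sex <- subset_specimens(dataset, keep)
    whole_aligned <- gpa_align(ds_sex)
    cells <- list()
    for (region in all_regions) {
      aligned <- if (region == "whole") {
        whole_aligned
      } else if (config$region_realign) {
        gpa_align(region_subset(ds_sex, region))
      } else {
        subset_region_alignment(whole_aligned, ds_sex, region)
      }
      consensus <- consensus_by_species_sex(aligned)
      shapes <- consensus_matrix(consensus, sex)
      sizes <- species_mean_sizes(aligned)
      cells[[region]] <- analyze_region_sex(shapes, sizes, config, region, sex, gen)
    }
    region_cmp <- if (multi_region) {
      compare_rates_regions(
        config$tree,
        setNames(lapply(region_names, function(r) cells[[r]]$shapes), region_names),
        n_sims = config$n_perm,
        seed = derive_seed(config$seed, stage_ids[["rates_regions"]] + 10000L * (sex == "female"))
      )
    }
    correlations <- if (multi_region) {
      rate_correlations(setNames(lapply(region_names, function(r) cells[[r]]$rates),
                                 region_names))
    }
    corrected <- if (config$allometry_corrected_rerun) {
      rerun_on_residuals(cells, config, gen)
    }
    per_sex[[sex]] <- list(cells = cells, region_comparison = region_cmp,
                           correlations = correlations,
                           allometry_corrected = corrected)
  }

  structure(
    list(
      table1 = build_table1(per_sex, config),
      region_rates = build_region_rates(per_sex),
      correlations = build_correlations(per_sex),
      allometry = build_allometry(per_sex),
      branch_rates = build_branch_rates(per_sex),
      per_sex = per_sex,
      metadata = list(
        package = "shaperate",
        version = as.character(utils::packageVersion("shaperate")),
        seed = config$seed, n_sims = config$n_sims, n_perm = config$n_perm,
        mode = config$mode, estimator = config$estimator,
        focal = config$focal, reference = config$reference,
        regions = all_regions, sexes = config$sexes,
        region_realign = config$region_realign
      )
    ),
    class = "analysis_report"
  )
}

# reuse whole-cranium alignment: subset the aligned coordinates (no re-GPA)
subset_region_alignment <- function(whole_aligned, dataset, region) {
  idx <- sort(dataset$regions$point_index[dataset$regions$region == region])
  out <- whole_aligned
  out$coords <- whole_aligned$coords[idx, , , drop = FALSE]
  out$mean_shape <- whole_aligned$mean_shape[idx, , drop = FALSE]
  out
}

rerun_on_residuals <- function(cells, config, gen) {
  purrr::imap(cells, function(cell, region) {
    fit <- phylo_allometry_fit(cell$shapes, cell$sizes, config$tree, lambda = 0,
                               n_perm = config$n_perm,
                               seed = derive_seed(config$seed, stage_ids[["allometry"]]))
    corrected <- allometry_residuals(fit)
    clade_map <- config$clades
    disparity <- disparity_report(
      corrected[names(clade_map)[clade_map == config$focal], , drop = FALSE],
      corrected[names(clade_map)[clade_map == config$reference], , drop = FALSE],
      n_perm = config$n_perm, seed = derive_seed(config$seed, stage_ids[["disparity"]])
    )
    bm_cmp <- compare_rates_two_groups(config$tree, corrected, clade_map,
                                       focal = config$focal, n_sims = config$n_perm,
                                       seed = derive_seed(config$seed, stage_ids[["rates_groups"]]))
    list(region = region, disparity = disparity, bm_cmp = bm_cmp)
  })
}

build_table1 <- function(per_sex, config) {
  purrr::map_dfr(names(per_sex), function(sex) {
    purrr::map_dfr(names(per_sex[[sex]]$cells), function(region) {
      cell <- per_sex[[sex]]$cells[[region]]
      tibble::tibble(
        sex = sex, region = region,
        pv_ratio = cell$disparity$pv_ratio, pv_p = cell$disparity$pv_p,
        distance_ratio = cell$disparity$distance_ratio,
        distance_p = cell$disparity$distance_p,
        excess_ratio = cell$excess_cmp$excess_ratio,
        excess_p = cell$excess_cmp$p_value,
        bm_rate_ratio = cell$bm_cmp$ratio,
        bm_rate_p = cell$bm_cmp$p_value
      )
    })
  })
}

build_region_rates <- function(per_sex) {
  purrr::map_dfr(names(per_sex), function(sex) {
    rc <- per_sex[[sex]]$region_comparison
    if (is.null(rc)) return(tibble::tibble())
    out <- rc$rates
    out$sex <- sex
    out$max_min_ratio <- rc$ratio
    out$p_value <- rc$p_value
    out[, c("sex", "region", "sigma2_mult", "max_min_ratio", "p_value")]
  })
}

build_correlations <- function(per_sex) {
  purrr::map_dfr(names(per_sex), function(sex) {
    cr <- per_sex[[sex]]$correlations
    if (is.null(cr)) return(tibble::tibble())
    cr$sex <- sex
    cr[, c("sex", setdiff(names(cr), "sex"))]
  })
}

build_allometry <- function(per_sex) {
  purrr::map_dfr(names(per_sex), function(sex) {
    purrr::map_dfr(per_sex[[sex]]$cells, function(cell) cell$allometry)
  })
}

build_branch_rates <- function(per_sex) {
  purrr::map_dfr(names(per_sex), function(sex) {
    purrr::map_dfr(names(per_sex[[sex]]$cells), function(region) {
      t <- per_sex[[sex]]$cells[[region]]$rates
      t$sex <- sex
      t$region <- region
      t[, c("sex", "region", "edge", "parent", "child", "child_label", "terminal",
            "clade", "d_obs", "d_exp", "R", "classification")]
    })
  })
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s regions x %s sexes (seed %d, %d sims, %d perms)\n",
              length(x$metadata$regions), length(x$metadata$sexes),
              x$metadata$seed, x$metadata$n_sims, x$metadata$n_perm))
  print(x$table1)
  invisible(x)
}

report_to_json_list <- function(report) {
  sort_keys <- function(x) {
    if (is.list(x) && !is.data.frame(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sort_keys)
    } else x
  }
  sort_keys(list(
    metadata = report$metadata,
    table1 = report$table1,
    region_rates = report$region_rates,
    correlations = report$correlations,
    allometry = report$allometry,
    branch_rates = report$branch_rates
  ))
}

#' Serialize an analysis report
#'
#' Writes the report as canonical JSON (sorted keys, full precision; two
#' runs with the same config and seed are byte-identical) and/or a set of
#' CSV tables mirroring the report layout (`table1.csv` with one
#' ratio/p-value column pair per statistic, plus branch rates, regional
#' rates, correlations and allometry fits).
#'
#' @param report an `analysis_report`
#' @param out_dir output directory (created if needed)
#' @param formats subset of `c("json", "csv")`
#' @return named vector of written paths, invisibly
#' @export
write_report <- function(report, out_dir, formats = c("json", "csv")) {
  stopifnot(inherits(report, "analysis_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory '%s'", out_dir),
                                  class = "shaperate_io")
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_to_json_list(report), p,
                         dataframe = "rows", digits = NA, auto_unbox = TRUE, pretty = TRUE)
    paths["json"] <- p
  }
  if ("csv" %in% formats) {
    tabs <- c("table1", "region_rates", "correlations", "allometry", "branch_rates")
    for (t in tabs) {
      p <- file.path(out_dir, paste0(t, ".csv"))
      utils::write.csv(as.data.frame(report[[t]]), p, row.names = FALSE)
      paths[t] <- p
    }
  }
  invisible(paths)
}

#' Validate a serialized report against the shipped schema
#'
#' Light structural validation of a `report.json` file against the JSON
#' schema in `inst/schema/analysis_report.schema.json`: required top-level
#' keys, required columns of each table, and value types.
#'
#' @param path path to a report JSON file
#' @return `TRUE` (invisibly) or an error describing the violation
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(system.file("schema", "analysis_report.schema.json",
                                            package = "shaperate"))
  x <- jsonlite::read_json(path)
  required <- names(schema$properties)
  missing <- setdiff(unlist(schema$required), names(x))
  if (length(missing)) abort(paste0("report missing keys: ", paste(missing, collapse = ", ")),
                             class = "shaperate_validation")
  for (tab in c("table1", "region_rates", "correlations", "allometry", "branch_rates")) {
    spec_cols <- unlist(schema$properties[[tab]]$items$required)
    rows <- x[[tab]]
    if (length(rows)) {
      have <- names(rows[[1]])
      miss <- setdiff(spec_cols, have)
      if (length(miss)) abort(sprintf("table '%s' missing columns: %s", tab,
                                      paste(miss, collapse = ", ")),
                              class = "shaperate_validation")
    }
  }
  invisible(TRUE)
}
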