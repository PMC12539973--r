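#' Observed ancestor-descendant shape change per branch
#'
#' Maps every node's PC score vector back to landmark space through the
#' shape PC model and computes the Procrustes distance between the two
#' endpoints of each branch. Tip rows of `states` are the observed scores,
#' so tip endpoints use the observed consensus coordinates exactly (the
#' full-basis back-transform reproduces them); alternatively the original
#' consensus matrix can be supplied via `tip_shapes`.
#'
#' @param model a [shape_pca()] model
#' @param tree the phylogeny the states were estimated on
#' @param states a `node_states` object covering all nodes
#' @param tip_shapes optional matrix of observed flattened tip shapes
#'   (rownames = tip labels) used verbatim for tip endpoints
#' @return tibble with per-branch columns `edge`, `parent`, `child`,
#'   `child_label`, `terminal`, `d_obs`
#' @export
observed_branch_changes <- function(model, tree, states, tip_shapes = NULL) {
  stopifnot(inherits(model, "shape_pc_model"), inherits(states, "node_states"))
  labs <- node_labels(tree)
  if (!all(labs %in% rownames(states$states))) {
    abort("node states do not cover all tree nodes", class = "shaperate_pipeline")
  }
  shapes <- pc_to_shape(model, states$states[labs, , drop = FALSE])
  rownames(shapes) <- labs
  if (!is.null(tip_shapes)) {
    common <- intersect(rownames(tip_shapes), tree$tip.label)
    shapes[common, ] <- tip_shapes[common, , drop = FALSE]
  }
  et <- edge_table(tree)
  diffs <- shapes[labs[et$child], , drop = FALSE] - shapes[labs[et$parent], , drop = FALSE]
  et$d_obs <- unname(sqrt(rowSums(diffs^2)))
  et[, c("edge", "parent", "child", "child_label", "terminal", "d_obs")]
}

#' Simulated neutral expectation of per-branch shape change
#'
#' Monte-Carlo expectation of the ancestor-descendant Procrustes distance
#' for every branch under constant-rate Brownian motion in PC space. Each
#' simulation starts at the observed root estimate and adds, along each
#' branch, independent Gaussian increments with per-component variance
#' `sigma2_j * n_gen(b)`. Node scores are then mapped back to landmark
#' coordinates and the distance between each branch's endpoints is recorded;
#' the expected distance `d_exp` is the arithmetic mean over simulations.
#'
#' With `mode = "true_node"` the simulated internal values are used
#' directly. With `mode = "reestimated"` the ancestral estimator is re-run
#' on the simulated tip values and branch changes are measured between
#' re-estimated ancestors (and simulated tips), mirroring what is done with
#' the observed data; `true_node` is the default, but note that comparing
#' estimated observed ancestors against true simulated ancestors biases
#' excess-change ratios downward, so `reestimated` is the apples-to-apples
#' choice for self-consistency checks.
#'
#' @param model a [shape_pca()] model
#' @param gen_tree a `generation_tree` from [rescale_to_generations()]
#' @param sigma2 per-component per-generation variances (one per retained PC)
#' @param root_scores PC score vector for the root (the observed root
#'   estimate)
#' @param n_sims number of simulations (default 100)
#' @param seed integer seed; results are deterministic given the seed
#' @param mode `"true_node"` or `"reestimated"`
#' @param estimator ancestral estimator for `reestimated` mode (`"bm"` uses
#'   the exact GLS operator; `"mvbm"` re-runs the iterative variable-rate
#'   estimator per simulation)
#' @param return_sims keep the full `n_sims x n_edge` distance matrix as
#'   attribute `"d_sims"`
#' @return tibble with per-branch `edge`, `parent`, `child`, `child_label`,
#'   `terminal`, `d_exp`, `n_sims`
#' @export
simulate_neutral_expectation <- function(model, gen_tree, sigma2, root_scores = NULL,
                                         n_sims = 100L, seed = 1L,
                                         mode = c("true_node", "reestimated"),
                                         estimator = c("bm", "mvbm"),
                                         return_sims = FALSE) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  stopifnot(inherits(model, "shape_pc_model"), inherits(gen_tree, "generation_tree"))
  tree <- gen_tree$gen_tree
  p <- ncol(model$basis)
  if (length(sigma2) != p) {
    abort(sprintf("sigma2 has %d entries but the model retains %d components",
                  length(sigma2), p), class = "shaperate_dimension")
  }
  if (all(sigma2 <= 0)) {
    abort("all per-component variances are zero: expected distances would be degenerate",
          class = "shaperate_degenerate_simulation")
  }
  if (n_sims < 1) abort("n_sims must be >= 1", class = "shaperate_validation")
  if (is.null(root_scores)) root_scores <- rep(0, p)
  stopifnot(length(root_scores) == p)

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  et <- edge_table(tree)
  preorder <- rev(ape::postorder(tree))

  set.seed(seed)
  # states[[node]]: n_sims x p matrix of simulated PC scores
  states <- vector("list", n_node)
  states[[n_tip + 1L]] <- matrix(root_scores, n_sims, p, byrow = TRUE)
  sd_edge <- sqrt(outer(et$length, sigma2)) # n_edge x p
  for (e in preorder) {
    incr <- matrix(rnorm(n_sims * p), n_sims, p) *
      matrix(sd_edge[e, ], n_sims, p, byrow = TRUE)
    states[[et$child[e]]] <- states[[et$parent[e]]] + incr
  }

  endpoint <- states
  if (mode == "reestimated") {
    if (estimator == "bm") {
      H <- bm_gls_operator(tree) # internal x tips
      tips_arr <- array(unlist(states[seq_len(n_tip)]), dim = c(n_sims, p, n_tip))
      for (node in (n_tip + 1L):n_node) {
        est <- matrix(0, n_sims, p)
        h <- H[node - n_tip, ]
        for (i in seq_len(n_tip)) est <- est + h[i] * tips_arr[, , i]
        endpoint[[node]] <- est
      }
    } else {
      for (s in seq_len(n_sims)) {
        tips <- t(vapply(seq_len(n_tip), function(i) states[[i]][s, ], numeric(p)))
        rownames(tips) <- tree$tip.label
        st <- mvbm_ancestral_states(tree, tips)$states
        for (node in (n_tip + 1L):n_node) {
          endpoint[[node]][s, ] <- st[paste0("node_", node), ]
        }
      }
    }
  }

  basis_t <- t(model$basis)
  d_sims <- matrix(0, n_sims, nrow(et))
  for (e in seq_len(nrow(et))) {
    diff_scores <- endpoint[[et$child[e]]] - endpoint[[et$parent[e]]]
    d_sims[, e] <- sqrt(rowSums((diff_scores %*% basis_t)^2))
  }
  out <- et[, c("edge", "parent", "child", "child_label", "terminal")]
  out$d_exp <- colMeans(d_sims)
  out$n_sims <- as.integer(n_sims)
  if (return_sims) attr(out, "d_sims") <- d_sims
  out
}

#' Branch-specific excess-change ratios
#'
#' Joins observed and expected per-branch distances and computes the
#' evolutionary rate `R(b) = d_obs(b) / d_exp(b)`. Branches with `R > 1`
#' accumulate more change than the neutral constant-rate expectation
#' (read as directional selection); `R < 1` indicates stabilizing
#' selection. Rates are unsigned.
#'
#' @param obs tibble from [observed_branch_changes()]
#' @param exp tibble from [simulate_neutral_expectation()]
#' @param clades optional per-edge clade labels (e.g. from
#'   [assign_branch_clades()]), in `obs` edge order
#' @return tibble of class `branch_rate_table` with columns `edge`,
#'   `parent`, `child`, `child_label`, `terminal`, `clade`, `d_obs`,
#'   `d_exp`, `R`, `classification`
#' @export
excess_change_table <- function(obs, exp, clades = NULL) {
  if (!setequal(obs$child_label, exp$child_label) || nrow(obs) != nrow(exp)) {
    abort("observed and expected tables cover different branch sets",
          class = "shaperate_validation")
  }
  exp <- exp[match(obs$child_label, exp$child_label), ]
  if (any(exp$d_exp == 0)) {
    abort(paste0("expected distance is zero for branch(es): ",
                 paste(obs$child_label[exp$d_exp == 0], collapse = ", ")),
          class = "shaperate_undefined_rate")
  }
  out <- obs[, c("edge", "parent", "child", "child_label", "terminal")]
  out$clade <- if (is.null(clades)) NA_character_ else clades
  out$d_obs <- obs$d_obs
  out$d_exp <- exp$d_exp
  out$R <- out$d_obs / out$d_exp
  out$classification <- dplyr::case_when(
    out$R > 1 ~ "directional",
    out$R < 1 ~ "stabilizing",
    TRUE ~ "expected"
  )
  class(out) <- c("branch_rate_table", class(out))
  out
}

#' Clade comparison of branch excess-change rates
#'
#' Compares the per-branch rates `R` of two clades with an exact Wilcoxon
#' rank-sum test and reports the clade excess-change ratio as the ratio of
#' mean branch rates (median-based ratio also reported).
#'
#' @param table a `branch_rate_table` with clade annotations
#' @param focal,reference clade labels to compare
#' @return one-row tibble with `excess_ratio`, `excess_ratio_median`,
#'   `p_value`, branch counts and mean rates
#' @export
excess_clade_comparison <- function(table, focal, reference) {
  r_f <- table$R[table$clade == focal]
  r_r <- table$R[table$clade == reference]
  if (length(r_f) < 1 || length(r_r) < 1) {
    abort("both clades need at least one branch", class = "shaperate_validation")
  }
  wt <- wilcoxon_rank_sum_exact(r_f, r_r)
  tibble::tibble(
    focal = focal, reference = reference,
    mean_r_focal = mean(r_f), mean_r_reference = mean(r_r),
    excess_ratio = mean(r_f) / mean(r_r),
    excess_ratio_median = stats::median(r_f) / stats::median(r_r),
    p_value = wt$p_value, test_exact = wt$exact,
    n_focal = length(r_f), n_reference = length(r_r)
  )
}

# Phylogenetic transform shared by the sigma2_mult family: the inverse
# square root of the BM tip covariance (by symmetric eigendecomposition)
# and the GLS root weights.
phylo_transform <- function(tree) {
  C <- ape::vcv(tree)
  eig <- eigen(C, symmetric = TRUE)
  if (any(eig$values < 1e-12 * max(eig$values))) {
    abort("phylogenetic covariance is numerically singular", class = "shaperate_numerical")
  }
  Cih <- eig$vectors %*% diag(1 / sqrt(eig$values), nrow(C)) %*% t(eig$vectors)
  Cinv <- eig$vectors %*% diag(1 / eig$values, nrow(C)) %*% t(eig$vectors)
  w <- Cinv %*% rep(1, nrow(C))
  list(C = C, Cih = Cih, w = as.vector(w), tips = rownames(C))
}

phylo_transformed_residuals <- function(pt, shapes) {
  Y <- as.matrix(shapes)[pt$tips, , drop = FALSE]
  root <- colSums(Y * pt$w) / sum(pt$w)
  Z <- pt$Cih %*% sweep(Y, 2, root)
  rownames(Z) <- pt$tips
  list(Z = Z, root = root)
}

#' Multivariate Brownian rate (sigma2_mult)
#'
#' The net multivariate Brownian-motion rate for high-dimensional shape
#' data: tip shapes are centered on the GLS root estimate, transformed by
#' the inverse square root of the BM tip covariance, and the rate is the
#' summed squared norm of the transformed rows divided by the number of
#' taxa. On a star phylogeny with unit branch lengths this reduces to the
#' ordinary (divisor-n) trace of the sample covariance. Reported in the
#' tree's native branch-length units.
#'
#' @param tree [ape::phylo] tree (tips must match the shape rownames)
#' @param shapes per-taxon flattened shape matrix (rownames = tip labels)
#' @return nonnegative scalar
#' @export
sigma2_mult <- function(tree, shapes) {
  shapes <- as.matrix(shapes)
  if (nrow(shapes) < 3) abort("at least 3 taxa required", class = "shaperate_insufficient_data")
  missing <- setdiff(tree$tip.label, rownames(shapes))
  if (length(missing)) abort(paste0("shapes missing for tips: ", paste(missing, collapse = ", ")),
                             class = "shaperate_validation")
  pt <- phylo_transform(tree)
  tr <- phylo_transformed_residuals(pt, shapes)
  sum(tr$Z^2) / nrow(tr$Z)
}

#' Compare multivariate Brownian rates between two clades
#'
#' Group rates are the per-group mean squared norms of the phylogenetically
#' transformed rows (the [sigma2_mult()] transformation restricted to each
#' group's taxa). The observed statistic is the focal/reference rate ratio.
#' The null distribution is obtained by simulating tip data on the full
#' tree under the single pooled rate (isotropic across coordinates) and
#' recomputing the ratio; the p-value compares absolute log-ratios with the
#' `(b+1)/(m+1)` convention. A label-permutation null is available as an
#' alternative.
#'
#' @param tree [ape::phylo] tree
#' @param shapes per-taxon flattened shape matrix (rownames = tip labels)
#' @param grouping named character vector: taxon -> clade (must partition
#'   the tips into two groups of >= 2 taxa)
#' @param focal focal clade label (defaults to the first group name)
#' @param n_sims simulations (or permutations) for the null (default 999)
#' @param seed integer seed
#' @param method `"simulation"` (BM-based) or `"permutation"`
#' @return one-row tibble with per-group rates, `ratio` (focal/reference)
#'   and `p_value`
#' @export
compare_rates_two_groups <- function(tree, shapes, grouping, focal = NULL,
                                     n_sims = 999L, seed = 1L,
                                     method = c("simulation", "permutation")) {
  method <- match.arg(method)
  shapes <- as.matrix(shapes)
  groups <- unique(unname(grouping[tree$tip.label]))
  if (length(groups) != 2 || anyNA(groups)) {
    abort("grouping must partition the tips into exactly two clades",
          class = "shaperate_validation")
  }
  focal <- focal %||% groups[1]
  reference <- setdiff(groups, focal)
  g <- unname(grouping[tree$tip.label])
  if (min(table(g)) < 2) abort("each group needs at least 2 taxa", class = "shaperate_validation")

  pt <- phylo_transform(tree)
  tr <- phylo_transformed_residuals(pt, shapes)
  n <- nrow(tr$Z); p <- ncol(tr$Z)
  row_ss <- rowSums(tr$Z^2)
  rate_of <- function(assign) {
    c(sum(row_ss[assign == focal]) / sum(assign == focal),
      sum(row_ss[assign == reference]) / sum(assign == reference))
  }
  obs <- rate_of(g)
  obs_ratio <- obs[1] / obs[2]
  pooled <- sum(row_ss) / n

  set.seed(seed)
  null_log <- if (method == "simulation") {
    L <- t(chol(pt$C))
    sd_dim <- sqrt(pooled / p)
    vapply(seq_len(n_sims), function(i) {
      Ysim <- L %*% matrix(rnorm(n * p, sd = sd_dim), n, p)
      rownames(Ysim) <- pt$tips
      trs <- phylo_transformed_residuals(pt, Ysim)
      ss <- rowSums(trs$Z^2)
      abs(log(sum(ss[g == focal]) / sum(g == focal)) -
            log(sum(ss[g == reference]) / sum(g == reference)))
    }, numeric(1))
  } else {
    vapply(seq_len(n_sims), function(i) {
      gp <- sample(g)
      r <- rate_of(gp)
      abs(log(r[1] / r[2]))
    }, numeric(1))
  }
  tibble::tibble(
    focal = focal, reference = reference,
    sigma2_focal = obs[1], sigma2_reference = obs[2],
    ratio = obs_ratio,
    p_value = perm_pvalue(null_log, abs(log(obs_ratio))),
    method = method, n_sims = as.integer(n_sims)
  )
}

#' Compare multivariate Brownian rates across anatomical regions
#'
#' Computes [sigma2_mult()] for every region on the same taxa and tests the
#' observed maximum/minimum rate ratio against a null in which all regions
#' evolve at a common rate. Null data preserve each region's dimensionality
#' and within-region evolutionary covariance (estimated from the
#' phylogenetically transformed data) but rescale it to the common (mean)
#' rate.
#'
#' @param tree [ape::phylo] tree
#' @param region_shapes named list of per-taxon shape matrices, one per
#'   region, identical taxa in each
#' @param n_sims simulations for the null (default 999)
#' @param seed integer seed
#' @return list of class `region_rate_comparison` with `rates` (tibble
#'   region, sigma2_mult), `ratio` (max/min), `p_value`, `n_sims`
#' @export
compare_rates_regions <- function(tree, region_shapes, n_sims = 999L, seed = 1L) {
  if (length(region_shapes) < 2) abort("need >= 2 regions", class = "shaperate_validation")
  taxa_sets <- lapply(region_shapes, rownames)
  if (!all(vapply(taxa_sets, setequal, logical(1), y = taxa_sets[[1]]))) {
    abort("regions must cover the same taxa", class = "shaperate_validation")
  }
  pt <- phylo_transform(tree)
  n <- length(pt$tips)
  trs <- lapply(region_shapes, function(s) phylo_transformed_residuals(pt, s))
  sig <- vapply(trs, function(tr) sum(tr$Z^2) / n, numeric(1))
  obs_ratio <- max(sig) / min(sig)
  common <- mean(sig)

  # low-rank factors of each region's evolutionary covariance, rescaled to
  # the common rate: Sigma_r = (Z'Z/n) * common/sigma_r = B_r B_r'
  L <- t(chol(pt$C))
  factors <- lapply(seq_along(trs), function(r) {
    sv <- svd(trs[[r]]$Z)
    keep <- sv$d > max(sv$d) * 1e-10
    sv$v[, keep, drop = FALSE] %*%
      diag(sv$d[keep] / sqrt(n) * sqrt(common / sig[r]), sum(keep))
  })
  set.seed(seed)
  null_ratios <- vapply(seq_len(n_sims), function(i) {
    sim_sig <- vapply(factors, function(B) {
      Ysim <- L %*% (matrix(rnorm(n * ncol(B)), n, ncol(B)) %*% t(B))
      rownames(Ysim) <- pt$tips
      tr <- phylo_transformed_residuals(pt, Ysim)
      sum(tr$Z^2) / n
    }, numeric(1))
    max(sim_sig) / min(sim_sig)
  }, numeric(1))
  structure(
    list(
      rates = tibble::tibble(region = names(region_shapes), sigma2_mult = unname(sig)),
      ratio = obs_ratio,
      p_value = perm_pvalue(null_ratios, obs_ratio),
      n_sims = as.integer(n_sims)
    ),
    class = "region_rate_comparison"
  )
}

#' @export
print.region_rate_comparison <- function(x, ...) {
  cat(sprintf("<region_rate_comparison> max/min ratio %.3g (p = %.4g, %d sims)\n",
              x$ratio, x$p_value, x$n_sims))
  print(x$rates)
  invisible(x)
}

#' Correlations between regional evolutionary rates
#'
#' Pearson correlations between per-branch excess-change rates of every
#' pair of regions, computed over all branches (`stratum = "combined"`) and
#' within each clade's branches (stem branches belong to their crown
#' clade). Two-sided t-based p-values; significance stars at 0.05 / 0.01 /
#' 0.001. Strata with fewer than 3 branches yield `NA`.
#'
#' @param tables named list of `branch_rate_table` tibbles (identical
#'   branch sets, clade column populated)
#' @return tibble of class `rate_correlations` with `region_a`, `region_b`,
#'   `stratum`, `n`, `r`, `p_value`, `stars`
#' @export
rate_correlations <- function(tables) {
  if (length(tables) < 2) abort("need >= 2 regions", class = "shaperate_validation")
  branch_sets <- lapply(tables, function(t) sort(t$child_label))
  if (!all(vapply(branch_sets, identical, logical(1), y = branch_sets[[1]]))) {
    abort("rate tables cover different branch sets", class = "shaperate_validation")
  }
  tables <- lapply(tables, function(t) t[order(t$child_label), ])
  clades <- setdiff(unique(tables[[1]]$clade), c(NA, "mixed"))
  strata <- c("combined", clades)
  regions <- names(tables)
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(strata, function(st) {
      sel <- if (st == "combined") rep(TRUE, nrow(tables[[1]])) else tables[[1]]$clade == st
      x <- tables[[pr[1]]]$R[sel]
      y <- tables[[pr[2]]]$R[sel]
      if (sum(sel) < 3 || sd(x) == 0 || sd(y) == 0) {
        return(tibble::tibble(region_a = pr[1], region_b = pr[2], stratum = st,
                              n = sum(sel), r = NA_real_, p_value = NA_real_,
                              stars = ""))
      }
      ct <- stats::cor.test(x, y, method = "pearson")
      tibble::tibble(
        region_a = pr[1], region_b = pr[2], stratum = st, n = sum(sel),
        r = unname(ct$estimate), p_value = ct$p.value,
        stars = significance_stars(ct$p.value)
      )
    })
  })
  class(rows) <- c("rate_correlations", class(rows))
  rows
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
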