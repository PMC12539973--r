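#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a landmark dataset into long format
#'
#' @param x a [landmark_dataset()]
#' @param ... unused
#' @return tibble with `specimen`, `point_index`, `x`, `y`, `z`, `region`,
#'   `species`, `sex`
#' @exportS3Method generics::tidy
#' @export
tidy.landmark_dataset <- function(x, ...) {
  k <- n_points(x); n <- n_specimens(x)
  ids <- dimnames(x$coords)[[3]]
  xs <- as.vector(x$coords[, 1, ])
  ys <- as.vector(x$coords[, 2, ])
  zs <- as.vector(x$coords[, 3, ])
  out <- tibble::tibble(
    specimen = rep(ids, each = k),
    point_index = rep(seq_len(k), n),
    x = xs, y = ys, z = zs
  )
  out <- dplyr::left_join(out, x$regions, by = "point_index")
  dplyr::left_join(out, x$specimens[, c("specimen", "species", "sex")], by = "specimen")
}

#' Tidy PC scores of a shape PC model
#'
#' @param x a [shape_pca()] model
#' @param ... unused
#' @return long tibble with `taxon`, `component`, `score`
#' @exportS3Method generics::tidy
#' @export
tidy.shape_pc_model <- function(x, ...) {
  scores <- tibble::as_tibble(x$scores, rownames = "taxon")
  tidyr::pivot_longer(scores, -"taxon", names_to = "component", values_to = "score")
}

#' One-row summary of a shape PC model
#'
#' @param x a [shape_pca()] model
#' @param ... unused
#' @return tibble with taxon count, coordinate count, retained components,
#'   total variance and the variance fraction of PC1
#' @exportS3Method generics::glance
#' @export
glance.shape_pc_model <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$taxa),
    n_coordinates = length(x$mean),
    n_components = ncol(x$basis),
    total_variance = sum(x$eigenvalues),
    prop_pc1 = x$eigenvalues[1] / sum(x$eigenvalues)
  )
}

#' Tidy an allometry fit
#'
#' @param x an [phylo_allometry_fit()] object
#' @param ... unused
#' @return per-taxon tibble with log size and the shape score along the
#'   fitted allometric axis (projection onto the slope direction)
#' @exportS3Method generics::tidy
#' @export
tidy.allometry_fit <- function(x, ...) {
  slope <- x$beta["log_size", ]
  axis <- slope / sqrt(sum(slope^2))
  proj <- as.vector((x$fitted + x$residuals -
                       matrix(x$beta["intercept", ], length(x$taxa),
                              ncol(x$fitted), byrow = TRUE)) %*% axis)
  tibble::tibble(
    taxon = x$taxa,
    log_size = log(unname(x$sizes)),
    allometric_score = proj,
    residual_norm = sqrt(rowSums(x$residuals^2))
  )
}

#' One-row summary of an allometry fit
#'
#' @param x an [phylo_allometry_fit()] object
#' @param ... unused
#' @return tibble with `lambda`, `r_squared`, `p_value`, `n_taxa`, `n_perm`
#' @exportS3Method generics::glance
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, r_squared = x$r_squared,
                 p_value = x$p_value, n_taxa = length(x$taxa),
                 n_perm = x$n_perm)
}

#' Tidy estimated node states
#'
#' @param x a `node_states` object
#' @param ... unused
#' @return long tibble with `node`, `trait`, `value` plus a `tip` flag
#' @exportS3Method generics::tidy
#' @export
tidy.node_states <- function(x, ...) {
  st <- tibble::as_tibble(x$states, rownames = "node")
  n_tip <- length(x$tree$tip.label)
  st$tip <- seq_len(nrow(st)) <= n_tip
  tidyr::pivot_longer(st, -c("node", "tip"), names_to = "trait", values_to = "value")
}

#' One-row summary of estimated node states
#'
#' @param x a `node_states` object
#' @param ... unused
#' @return tibble with node/trait counts, scalar spread and convergence
#' @exportS3Method generics::glance
#' @export
glance.node_states <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$states), n_traits = ncol(x$states),
    scalar_min = min(x$branch_scalars), scalar_max = max(x$branch_scalars),
    converged = x$converged, iterations = x$iterations
  )
}
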