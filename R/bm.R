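# Shared-path-length covariances between internal nodes and tips: entry
# (i, j) is the depth (root-to-node path length) of the MRCA of internal
# node i and tip j, i.e. Cov(node_i, tip_j) under unit-rate BM.
node_tip_covariance <- function(tree) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  # mrca of every node pair (tips + internal)
  m <- ape::mrca(tree, full = TRUE)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  matrix(depths[m[internal, seq_len(n_tip), drop = FALSE]],
         nrow = length(internal), ncol = n_tip,
         dimnames = list(paste0("node_", internal), tree$tip.label))
}

# Linear operator H mapping tip values to GLS estimates at internal nodes
# (root first): states_internal = H %*% Y. Exact generalized least squares
# under Brownian motion with the root treated as the GLS grand mean.
bm_gls_operator <- function(tree) {
  n_tip <- length(tree$tip.label)
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  one <- rep(1, n_tip)
  w <- Cinv %*% one
  root_row <- t(w) / sum(w)                    # 1 x n
  V <- node_tip_covariance(tree)               # m x n, row 1 = root
  H <- matrix(rep(root_row, tree$Nnode), nrow = tree$Nnode, byrow = TRUE) +
    V %*% Cinv %*% (diag(n_tip) - one %*% root_row)
  rownames(H) <- rownames(V)
  colnames(H) <- tree$tip.label
  H
}

new_node_states <- function(tree, states, scalars, converged = TRUE, iterations = 0L) {
  structure(
    list(states = states, branch_scalars = scalars, converged = converged,
         iterations = iterations, tree = tree),
    class = "node_states"
  )
}

#' @export
print.node_states <- function(x, ...) {
  cat(sprintf("<node_states> %d nodes x %d traits; scalar range [%.3g, %.3g]%s\n",
              nrow(x$states), ncol(x$states),
              min(x$branch_scalars), max(x$branch_scalars),
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Brownian-motion ancestral states by generalized least squares
#'
#' Exact GLS estimates under constant-rate Brownian motion: the root is the
#' GLS grand mean `(1' C^-1 1)^-1 1' C^-1 Y` with `C` the tip covariance of
#' shared path lengths, and every internal node is the conditional
#' expectation of its state given the tips. Traits (columns) are estimated
#' independently.
#'
#' @param tree rooted binary [ape::phylo] tree with branch lengths
#' @param tip_values numeric matrix of tip trait values (rownames = tip
#'   labels), or a vector for a single trait
#' @return object of class `node_states`: `states` is a `(n_tip + n_node) x
#'   p` matrix (tip rows equal the input exactly; rownames are tip labels
#'   then `node_<number>`), `branch_scalars` are all 1.
#' @export
bm_ancestral_states <- function(tree, tip_values) {
  if (!is.matrix(tip_values)) tip_values <- matrix(tip_values, ncol = 1,
                                                   dimnames = list(names(tip_values), NULL))
  missing <- setdiff(tree$tip.label, rownames(tip_values))
  if (length(missing)) {
    abort(paste0("tip values missing for: ", paste(missing, collapse = ", ")),
          class = "shaperate_validation")
  }
  if (!all(is.finite(tip_values))) abort("tip values must be finite", class = "shaperate_validation")
  Y <- tip_values[tree$tip.label, , drop = FALSE]
  H <- tryCatch(bm_gls_operator(tree), error = function(e) {
    abort(paste0("singular phylogenetic covariance (duplicate zero-length tips?): ",
                 conditionMessage(e)), class = "shaperate_numerical")
  })
  internal <- H %*% Y
  states <- rbind(Y, internal)
  rownames(states) <- node_labels(tree)
  new_node_states(tree, states, rep(1, nrow(tree$edge)))
}

#' Multiple-variance Brownian-motion ancestral states
#'
#' Variable-rate ancestral state estimation: each branch carries a variance
#' scalar `s_b` (mean 1 across branches) multiplying its length. States are
#' re-estimated under the current effective branch lengths; each branch's
#' local rate (mean squared per-trait change along the branch divided by the
#' branch's current effective length) is compared with the global mean rate,
#' and the scalar of a branch is updated multiplicatively toward the
#' local/global ratio with damping 0.5 *only* when its standardized local
#' rate falls outside the central chi-square band expected under rate
#' homogeneity (`p * ratio ~ chi^2_p`, band `band_alpha`). Scalars are then
#' renormalized to mean 1, and iteration stops when the largest scalar
#' change falls below `tol` or `max_iter` is reached. The gate is what makes
#' the estimator collapse onto the standard constant-rate BM estimate when
#' rates do not differ: with homogeneous data essentially no branch escapes
#' the band, the scalars stay at 1, and the states equal the plain GLS
#' states; an always-on update would instead chase the sampling noise of
#' per-branch changes all the way to a rate-equalizing fixed point. This
#' iterative rescaling is this package's concrete definition of the mvBM
#' estimator; plain [bm_ancestral_states()] is the zero-iteration special
#' case and the recommended fallback.
#'
#' @inheritParams bm_ancestral_states
#' @param tol convergence tolerance on the maximum absolute scalar change
#' @param max_iter maximum number of iterations (0 returns plain BM states)
#' @param damping exponent applied to the local/global rate ratio per update
#' @param band_alpha two-sided tail mass of the homogeneity band: a branch
#'   is adjusted only when `p * local/global` leaves the central
#'   `1 - band_alpha` chi-square interval (default 0.02)
#' @param scalar_floor lower bound for branch scalars (guards against
#'   zero-length effective branches)
#' @return a `node_states` object with per-branch `branch_scalars` and a
#'   `converged` flag
#' @export
mvbm_ancestral_states <- function(tree, tip_values, tol = 1e-4, max_iter = 50L,
                                  damping = 0.5, band_alpha = 0.02,
                                  scalar_floor = 1e-4) {
  if (!is.matrix(tip_values)) tip_values <- matrix(tip_values, ncol = 1,
                                                   dimnames = list(names(tip_values), NULL))
  base <- bm_ancestral_states(tree, tip_values)
  if (max_iter < 1) return(base)
  n_edge <- nrow(tree$edge)
  p <- ncol(tip_values)
  s <- rep(1, n_edge)
  t_b <- tree$edge.length
  states <- base$states
  converged <- FALSE
  iter <- 0L
  band <- stats::qchisq(c(band_alpha / 2, 1 - band_alpha / 2), df = p) / p
  for (iter in seq_len(max_iter)) {
    work <- tree
    work$edge.length <- t_b * s
    st <- bm_ancestral_states(work, tip_values)$states
    d2 <- rowSums((st[tree$edge[, 2], , drop = FALSE] -
                     st[tree$edge[, 1], , drop = FALSE])^2) / p
    local_rate <- pmax(d2 / (t_b * s), 1e-300)
    global_rate <- mean(local_rate)
    ratio <- local_rate / global_rate
    adjust <- ratio < band[1] | ratio > band[2]
    s_new <- ifelse(adjust, s * ratio^damping, s)
    s_new <- pmax(s_new, scalar_floor)
    s_new <- s_new / mean(s_new)
    delta <- max(abs(s_new - s))
    s <- s_new
    states <- st
    if (delta < tol) { converged <- TRUE; break }
  }
  new_node_states(tree, states, s, converged = converged, iterations = iter)
}

#' Per-trait Brownian rate from independent contrasts
#'
#' The BM rate estimate for one scalar trait: the mean of the squared
#' phylogenetically independent contrasts (each contrast standardized by its
#' expected standard deviation). Applied per principal component on the
#' generation-scaled tree this yields the per-generation variance of each
#' component.
#'
#' @param tree [ape::phylo] tree with branch lengths (e.g. in generations)
#' @param tip_values named numeric vector of tip values
#' @return nonnegative scalar rate
#' @export
pic_rate_per_trait <- function(tree, tip_values) {
  if (length(tree$tip.label) < 2) abort("at least 2 tips required", class = "shaperate_insufficient_data")
  x <- tip_values[tree$tip.label]
  if (anyNA(x)) abort("tip values missing for some tips", class = "shaperate_validation")
  contrasts <- ape::pic(x, tree)
  mean(contrasts^2)
}

#' Per-generation variance for every principal component
#'
#' @param gen_tree a `generation_tree` from [rescale_to_generations()]
#' @param scores per-taxon PC score matrix (rownames = tip labels)
#' @return numeric vector of per-generation variances, one per column
#' @export
per_generation_variance <- function(gen_tree, scores) {
  stopifnot(inherits(gen_tree, "generation_tree"))
  apply(as.matrix(scores), 2, function(x) {
    pic_rate_per_trait(gen_tree$gen_tree, setNames(x, rownames(scores)))
  })
}
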