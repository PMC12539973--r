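#' Principal component model of shape variation
#'
#' Eigendecomposition of the centered covariance of per-taxon flattened
#' Procrustes coordinates (covariance PCA; coordinates share units).
#' All components with nonzero variance are retained. Eigenvalues use the
#' divisor-n convention so their sum equals the mean squared Procrustes
#' distance of the taxa from the mean shape. Sign convention: each
#' component's largest-magnitude loading is positive.
#'
#' @param x numeric matrix of flattened shapes, taxa in rows (rownames used
#'   as taxon labels)
#' @return object of class `shape_pc_model` with elements `mean` (length-p
#'   mean shape), `basis` (`p x r` orthonormal matrix), `eigenvalues`
#'   (length r, nonincreasing), `scores` (`n x r`, rownames = taxa) and
#'   `taxa`.
#' @export
shape_pca <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) abort("at least 2 taxa are required for PCA", class = "shaperate_insufficient_data")
  taxa <- rownames(x) %||% paste0("taxon_", seq_len(n))
  mu <- colMeans(x)
  cen <- sweep(x, 2, mu)
  sv <- svd(cen)
  keep <- sv$d > max(sv$d, 0) * 1e-10 & sv$d > 1e-300
  r <- sum(keep)
  basis <- sv$v[, keep, drop = FALSE]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], r, r)
  # largest-magnitude loading positive
  for (j in seq_len(r)) {
    i_max <- which.max(abs(basis[, j]))
    if (basis[i_max, j] < 0) {
      basis[, j] <- -basis[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- taxa
  colnames(scores) <- paste0("PC", seq_len(r))
  colnames(basis) <- paste0("PC", seq_len(r))
  structure(
    list(mean = unname(mu), basis = basis, eigenvalues = sv$d[keep]^2 / n,
         scores = scores, taxa = taxa),
    class = "shape_pc_model"
  )
}

#' @export
print.shape_pc_model <- function(x, ...) {
  cat(sprintf("<shape_pc_model> %d taxa, %d coordinates, %d components (total variance %.3g)\n",
              length(x$taxa), length(x$mean), ncol(x$basis), sum(x$eigenvalues)))
  invisible(x)
}

#' Back-transform PC scores to a flattened shape
#'
#' `mean + scores %*% t(basis)`; the exact inverse of the PCA projection
#' when all components are supplied. Shorter score vectors are padded with
#' zeros on the trailing components.
#'
#' @param model a [shape_pca()] model
#' @param scores numeric vector (length <= number of components) or matrix
#'   with one row per shape
#' @return flattened shape vector, or matrix with one row per input row
#' @export
pc_to_shape <- function(model, scores) {
  stopifnot(inherits(model, "shape_pc_model"))
  vec_in <- !is.matrix(scores)
  scores <- if (vec_in) matrix(scores, nrow = 1) else as.matrix(scores)
  r <- ncol(model$basis)
  if (ncol(scores) > r) {
    abort(sprintf("score vector has %d entries but the model has %d components",
                  ncol(scores), r), class = "shaperate_dimension")
  }
  if (ncol(scores) < r) {
    scores <- cbind(scores, matrix(0, nrow(scores), r - ncol(scores)))
  }
  out <- sweep(scores %*% t(model$basis), 2, model$mean, `+`)
  if (vec_in) drop(out) else out
}
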