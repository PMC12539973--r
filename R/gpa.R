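#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid; the standard geometric-morphometric size measure.
#'
#' @param config `k x 3` (or `k x d`) numeric matrix
#' @return nonnegative scalar
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  cen <- sweep(config, 2, colMeans(config))
  sqrt(sum(cen^2))
}

center_config <- function(config) sweep(config, 2, colMeans(config))

# optimal proper rotation R minimizing ||x %*% R - target||_F (no reflection)
optimal_rotation <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  d <- diag(c(rep(1, ncol(m) - 1), sign(det(sv$u %*% t(sv$v)))))
  sv$u %*% d %*% t(sv$v)
}

#' Generalized Procrustes alignment
#'
#' Removes translation (centering), size (each configuration scaled to unit
#' centroid size) and orientation (proper rotations only, no reflections) by
#' iteratively rotating all configurations to their updated mean shape until
#' the mean changes by less than `tol` or `max_iter` iterations.
#'
#' @param configs a `landmark_dataset`, a `k x 3 x n` array, or a list of
#'   `k x 3` matrices
#' @param tol convergence tolerance on the root summed squared change of the
#'   mean shape (default 1e-10)
#' @param max_iter maximum number of iterations (default 100)
#' @return an object of class `aligned_shapes` with elements `coords`
#'   (aligned `k x 3 x n` array, each with centroid at the origin and unit
#'   centroid size), `centroid_sizes` (original sizes, named), `mean_shape`
#'   (consensus configuration, unit centroid size) and `iterations`.
#' @export
gpa_align <- function(configs, tol = 1e-10, max_iter = 100L) {
  dataset <- NULL
  if (inherits(configs, "landmark_dataset")) {
    dataset <- configs
    configs <- configs$coords
  }
  if (is.list(configs) && !is.array(configs)) {
    nm <- names(configs)
    configs <- array(unlist(configs), dim = c(nrow(configs[[1]]), ncol(configs[[1]]), length(configs)),
                     dimnames = list(NULL, NULL, nm))
  }
  k <- dim(configs)[1]; n <- dim(configs)[3]
  if (k < 3) abort("at least 3 points are required for alignment", class = "shaperate_geometry")
  ids <- dimnames(configs)[[3]] %||% paste0("specimen_", seq_len(n))

  cs <- numeric(n)
  aligned <- array(0, dim = dim(configs), dimnames = list(NULL, c("x", "y", "z"), ids))
  for (i in seq_len(n)) {
    x <- center_config(configs[, , i])
    s <- sqrt(sum(x^2))
    if (s < 1e-12) {
      abort(sprintf("degenerate configuration '%s': all points coincident", ids[i]),
            class = "shaperate_geometry")
    }
    cs[i] <- s
    aligned[, , i] <- x / s
  }
  names(cs) <- ids

  # start from the arithmetic mean so an already-aligned set is a fixed
  # point (idempotence); fall back to the first shape if the raw mean is
  # degenerate (e.g. random orientations cancelling out)
  mean_shape <- apply(aligned, c(1, 2), mean)
  if (sqrt(sum(mean_shape^2)) < 0.1) mean_shape <- aligned[, , 1]
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], mean_shape)
    }
    new_mean <- apply(aligned, c(1, 2), mean)
    new_mean <- center_config(new_mean)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || iter >= max_iter) break
  }

  structure(
    list(coords = aligned, centroid_sizes = cs, mean_shape = mean_shape,
         iterations = iter, specimens = dataset$specimens, regions = dataset$regions),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("<aligned_shapes> %d configurations x %d points (GPA, %d iterations)\n",
              dim(x$coords)[3], dim(x$coords)[1], x$iterations))
  invisible(x)
}

#' Procrustes distance between two superimposed shapes
#'
#' The square root of the summed squared distances between homologous points,
#' i.e. the Euclidean norm of the difference of the flattened configurations,
#' which must already be in a common aligned frame.
#'
#' @param a,b flattened shape vectors (or `k x 3` matrices) of equal length
#' @return nonnegative scalar
#' @export
procrustes_distance <- function(a, b) {
  a <- if (is.matrix(a)) flatten_config(a) else as.numeric(a)
  b <- if (is.matrix(b)) flatten_config(b) else as.numeric(b)
  if (length(a) != length(b)) {
    abort(sprintf("dimension mismatch: %d vs %d", length(a), length(b)),
          class = "shaperate_dimension")
  }
  sqrt(sum((a - b)^2))
}

#' Species-by-sex consensus shapes
#'
#' Within each (species, sex) cell, if subspecies labels are present the
#' subspecies means are computed first and then averaged with equal weight
#' (grand mean); otherwise the consensus is the plain arithmetic mean of the
#' aligned specimens. Empty cells are omitted with a warning.
#'
#' @param aligned an `aligned_shapes` object (from [gpa_align()])
#' @param metadata specimen metadata data frame (`specimen,species,sex`,
#'   optional `subspecies`); defaults to the metadata carried by `aligned`
#' @return tibble with columns `species`, `sex`, `n_specimens` and `shape`
#'   (list-column of flattened consensus vectors), of class `consensus_shapes`
#' @export
consensus_by_species_sex <- function(aligned, metadata = NULL) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  metadata <- tibble::as_tibble(metadata %||% aligned$specimens)
  if (is.null(metadata)) abort("specimen metadata required", class = "shaperate_validation")
  if (!"subspecies" %in% names(metadata)) metadata$subspecies <- NA_character_
  ids <- dimnames(aligned$coords)[[3]]
  missing <- setdiff(ids, metadata$specimen)
  if (length(missing)) {
    abort(paste0("metadata missing for specimens: ", paste(missing, collapse = ", ")),
          class = "shaperate_validation")
  }
  metadata <- metadata[match(ids, metadata$specimen), ]
  flat <- t(apply(aligned$coords, 3, flatten_config))

  cells <- unique(metadata[, c("species", "sex")])
  cells <- cells[order(cells$species, cells$sex), ]
  out <- purrr::pmap(cells, function(species, sex) {
    sel <- metadata$species == species & metadata$sex == sex
    if (!any(sel)) {
      warn(sprintf("empty group %s/%s omitted", species, sex))
      return(NULL)
    }
    sub <- metadata$subspecies[sel]
    block <- flat[sel, , drop = FALSE]
    if (all(is.na(sub)) || length(unique(sub)) == 1L) {
      shape <- colMeans(block)
    } else {
      # grand mean: average subspecies means with equal weight
      sub[is.na(sub)] <- "<none>"
      sub_means <- rowsum(block, sub) / as.vector(table(sub)[sort(unique(sub))])
      shape <- colMeans(sub_means)
    }
    tibble::tibble(species = species, sex = sex, n_specimens = sum(sel),
                   shape = list(unname(shape)))
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("consensus_shapes", class(res))
  res
}

#' Extract a per-taxon shape matrix for one sex
#'
#' @param consensus output of [consensus_by_species_sex()]
#' @param sex `"male"` or `"female"` (or `NULL` for all rows, named
#'   `species|sex`)
#' @return numeric matrix, taxa in rows (rownames = species), flattened shape
#'   coordinates in columns
#' @export
consensus_matrix <- function(consensus, sex = NULL) {
  rows <- if (is.null(sex)) consensus else consensus[consensus$sex == sex, ]
  if (!nrow(rows)) abort(sprintf("no consensus rows for sex '%s'", sex),
                         class = "shaperate_validation")
  m <- do.call(rbind, rows$shape)
  rownames(m) <- if (is.null(sex)) paste(rows$species, rows$sex, sep = "|") else rows$species
  m
}
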