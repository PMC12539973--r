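#' Procrustes variance of a group of shapes
#'
#' Mean squared Procrustes distance of group members from the group mean
#' shape: `(1/n) * sum_i ||x_i - xbar||^2`, equivalent to the trace of the
#' group covariance matrix with divisor n. The standard morphometric
#' disparity measure.
#'
#' @param group numeric matrix of flattened shapes, taxa in rows
#' @return nonnegative scalar
#' @export
procrustes_variance <- function(group) {
  group <- as.matrix(group)
  n <- nrow(group)
  if (n < 2) abort("at least 2 shapes are required", class = "shaperate_insufficient_data")
  cen <- sweep(group, 2, colMeans(group))
  sum(cen^2) / n
}

#' Permutation test for a disparity (Procrustes variance) ratio
#'
#' The observed statistic is `|PV(A) - PV(B)|`; taxa are permuted across the
#' two groups preserving group sizes, and the p-value is
#' `(count of permuted statistics >= observed + 1) / (n_perm + 1)`.
#'
#' @param group_a,group_b numeric shape matrices (taxa in rows; rownames must
#'   not overlap)
#' @param n_perm number of permutations (>= 99; default 999)
#' @param seed integer seed (the test is deterministic given the seed)
#' @return tibble with `pv_a`, `pv_b`, `ratio` (`PV(A)/PV(B)`), `statistic`
#'   and `p_value`
#' @export
disparity_ratio_test <- function(group_a, group_b, n_perm = 999L, seed = 1L) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (n_perm < 99) abort("n_perm must be >= 99", class = "shaperate_validation")
  ra <- rownames(group_a); rb <- rownames(group_b)
  if (!is.null(ra) && !is.null(rb) && length(intersect(ra, rb))) {
    abort("groups share taxon ids", class = "shaperate_validation")
  }
  pv_a <- procrustes_variance(group_a)
  pv_b <- procrustes_variance(group_b)
  observed <- abs(pv_a - pv_b)
  pooled <- rbind(group_a, group_b)
  na <- nrow(group_a); n <- nrow(pooled)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    abs(procrustes_variance(pooled[idx, , drop = FALSE]) -
          procrustes_variance(pooled[-idx, , drop = FALSE]))
  }, numeric(1))
  tibble::tibble(
    pv_a = pv_a, pv_b = pv_b, ratio = pv_a / pv_b,
    statistic = observed, p_value = perm_pvalue(null_stats, observed),
    n_perm = as.integer(n_perm)
  )
}

#' Pairwise Procrustes distances within a group
#'
#' All unordered pairs of taxa, each counted once (`m(m-1)/2` distances).
#'
#' @param group numeric shape matrix, taxa in rows
#' @return numeric vector of distances, named `taxon1:taxon2` when rownames
#'   are available
#' @export
pairwise_distance_distribution <- function(group) {
  group <- as.matrix(group)
  n <- nrow(group)
  if (n < 2) abort("at least 2 shapes are required", class = "shaperate_insufficient_data")
  d <- as.vector(stats::dist(group))
  nm <- rownames(group)
  if (!is.null(nm)) {
    # stats::dist orders pairs column-major by the first index
    names(d) <- paste(rep(nm[-n], times = (n - 1):1),
                      unlist(lapply(2:n, function(i) nm[i:n])), sep = ":")
  }
  d
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test. The p-value is computed from the exact null
#' rank-sum distribution when `n_x + n_y <= 25` and there are no ties;
#' otherwise mid-ranks with a normal approximation and continuity correction
#' are used and the result is flagged `exact = FALSE`.
#'
#' @param x,y numeric samples
#' @return tibble with `statistic` (rank-sum W of `x`), `u` (Mann-Whitney U),
#'   `p_value` and `exact`
#' @export
wilcoxon_rank_sum_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) abort("both samples must be nonempty", class = "shaperate_validation")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  ties <- length(unique(c(x, y))) < nx + ny
  if (!ties && nx + ny <= 25) {
    p_lower <- stats::pwilcox(u, nx, ny)
    p_upper <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lower, p_upper))
    exact <- TRUE
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 * (nx + ny + 1 - sum(tie_tab^3 - tie_tab) /
                                ((nx + ny) * (nx + ny - 1)))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  tibble::tibble(statistic = w, u = u, p_value = p, exact = exact)
}

#' Clade disparity report
#'
#' The disparity battery for one pair of clades: Procrustes variance ratio
#' with its permutation test, and the clade-wise pairwise Procrustes distance
#' distributions compared by an exact Wilcoxon rank-sum test. The printed
#' distance ratio uses distribution means; the median-based ratio is also
#' reported.
#'
#' @param focal,reference shape matrices (taxa in rows) for the focal and
#'   reference clades
#' @param n_perm permutations for the variance test
#' @param seed integer seed
#' @return tibble (one row) with ratio/p-value columns
#' @export
disparity_report <- function(focal, reference, n_perm = 999L, seed = 1L) {
  pv <- disparity_ratio_test(focal, reference, n_perm = n_perm, seed = seed)
  d_f <- pairwise_distance_distribution(focal)
  d_r <- pairwise_distance_distribution(reference)
  wt <- wilcoxon_rank_sum_exact(d_f, d_r)
  tibble::tibble(
    pv_focal = pv$pv_a, pv_reference = pv$pv_b,
    pv_ratio = pv$ratio, pv_p = pv$p_value,
    distance_ratio = mean(d_f) / mean(d_r),
    distance_ratio_median = stats::median(d_f) / stats::median(d_r),
    distance_p = wt$p_value, distance_test_exact = wt$exact,
    n_pairs_focal = length(d_f), n_pairs_reference = length(d_r)
  )
}
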