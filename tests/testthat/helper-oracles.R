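# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and, where possible, the same ape primitives) so each check
# compares two independent routes to the same quantity.

# naive coordinate-wise accumulation of the Procrustes distance
oracle_distance_loop <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s)
}

# trace of the (divisor-n) covariance matrix
oracle_pv_trace <- function(x) {
  n <- nrow(x)
  sum(diag(stats::cov(x))) * (n - 1) / n
}

# exhaustive enumeration of the two-sided Wilcoxon rank-sum p-value
oracle_wilcoxon_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# full joint-covariance conditional-mean BM ancestral states, built by
# explicit path walking on the edge matrix (no ape::vcv / ape::mrca)
oracle_bm_states <- function(tree, y) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  parent <- integer(n_node); parent[] <- NA
  elen <- numeric(n_node)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- n_tip + 1L
  path_to_root <- function(v) {
    out <- c()
    while (!is.na(parent[v])) { out <- c(out, v); v <- parent[v] }
    out
  }
  depth <- function(v) sum(elen[path_to_root(v)])
  shared <- function(u, v) {
    pu <- path_to_root(u); pv <- path_to_root(v)
    sum(elen[intersect(pu, pv)])
  }
  C <- matrix(0, n_tip, n_tip)
  for (i in seq_len(n_tip)) for (j in seq_len(n_tip)) {
    C[i, j] <- if (i == j) depth(i) else shared(i, j)
  }
  y <- as.matrix(y)[tree$tip.label, , drop = FALSE]
  Cinv <- solve(C)
  one <- rep(1, n_tip)
  a0 <- drop(t(one) %*% Cinv %*% y) / drop(t(one) %*% Cinv %*% one)
  states <- matrix(NA_real_, n_node, ncol(y))
  states[seq_len(n_tip), ] <- y
  for (v in (n_tip + 1L):n_node) {
    cv <- vapply(seq_len(n_tip), function(tip) shared(v, tip), numeric(1))
    states[v, ] <- a0 + drop(t(cv) %*% Cinv %*% sweep(y, 2, a0))
  }
  rownames(states) <- c(tree$tip.label, paste0("node_", (n_tip + 1L):n_node))
  states
}

# brute-force GPA objective for three planar configurations: fix the first,
# grid-search in-plane rotation angle and flip of the other two (a 3D proper
# rotation acting on planar shapes can realize an in-plane reflection), and
# return the minimal summed squared deviation from the arithmetic mean.
oracle_gpa_planar <- function(configs) {
  pre <- lapply(configs, function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  })
  rot2 <- function(x, theta, flip) {
    xy <- x[, 1:2]
    if (flip) xy[, 2] <- -xy[, 2]
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    cbind(xy %*% R, x[, 3])
  }
  objective <- function(par, flips) {
    xs <- list(pre[[1]], rot2(pre[[2]], par[1], flips[1]),
               rot2(pre[[3]], par[2], flips[2]))
    m <- Reduce(`+`, xs) / 3
    sum(vapply(xs, function(x) sum((x - m)^2), numeric(1)))
  }
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 73)
  for (f1 in c(FALSE, TRUE)) for (f2 in c(FALSE, TRUE)) {
    coarse <- expand.grid(t1 = grid, t2 = grid)
    vals <- apply(coarse, 1, function(p) objective(p, c(f1, f2)))
    start <- unlist(coarse[which.min(vals), ])
    # nested refinement down to 1e-7 in angle
    width <- diff(grid[1:2])
    par <- start
    for (lev in 1:8) {
      g1 <- seq(par[1] - width, par[1] + width, length.out = 21)
      g2 <- seq(par[2] - width, par[2] + width, length.out = 21)
      cand <- expand.grid(t1 = g1, t2 = g2)
      vals <- apply(cand, 1, function(p) objective(p, c(f1, f2)))
      par <- unlist(cand[which.min(vals), ])
      width <- width / 8
    }
    best <- min(best, objective(par, c(f1, f2)))
  }
  best
}

# ordinary least squares regression of each shape column on centered log
# size via explicit normal equations
oracle_ols_fit <- function(Y, x) {
  xc <- x - mean(x)
  X <- cbind(1, xc)
  beta <- solve(t(X) %*% X) %*% t(X) %*% Y
  fitted <- X %*% beta
  res <- Y - fitted
  ss_res <- sum(res^2)
  yc <- sweep(Y, 2, colMeans(Y))
  list(beta = beta, r2 = 1 - ss_res / sum(yc^2), residuals = res)
}

# brute-force GLS fit with full covariance C (lambda = 1 PGLS oracle)
oracle_pgls_fit <- function(Y, x, C) {
  xc <- x - mean(x)
  X <- cbind(1, xc)
  Cinv <- solve(C)
  beta <- solve(t(X) %*% Cinv %*% X) %*% t(X) %*% Cinv %*% Y
  res <- Y - X %*% beta
  beta0 <- solve(t(X[, 1, drop = FALSE]) %*% Cinv %*% X[, 1, drop = FALSE]) %*%
    t(X[, 1, drop = FALSE]) %*% Cinv %*% Y
  res0 <- Y - X[, 1, drop = FALSE] %*% beta0
  list(beta = beta,
       r2 = 1 - sum(diag(t(res) %*% Cinv %*% res)) /
         sum(diag(t(res0) %*% Cinv %*% res0)))
}

# small test trees (<= 6 tips), all rooted and binary with branch lengths
oracle_test_trees <- function() {
  list(
    two_tip = ape::read.tree(text = "(A:1,B:1);"),
    two_tip_uneven = ape::read.tree(text = "(A:0.5,B:2);"),
    three = ape::read.tree(text = "((A:1,B:1):1,C:2);"),
    four = ape::read.tree(text = "((A:1,B:2):0.5,(C:0.7,D:1.5):1);"),
    five = ape::read.tree(text = "(((A:0.4,B:0.6):0.5,C:1.2):0.8,(D:0.9,E:0.3):1.1);"),
    six = ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  )
}
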