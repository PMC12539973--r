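test_that("centroid size: hand values, homogeneity, degenerate point", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(centroid_size(square), sqrt(2))
  set.seed(1)
  cfg <- matrix(rnorm(30), 10, 3)
  expect_equal(centroid_size(cfg * 2), 2 * centroid_size(cfg))
  expect_equal(centroid_size(matrix(c(3, 4, 5), 1, 3)), 0)
})

test_that("single configuration aligns to itself centered at unit size", {
  cfg <- matrix(rnorm(12), 4, 3) + 5
  al <- gpa_align(list(a = cfg))
  expect_equal(colMeans(al$coords[, , 1]), c(0, 0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(centroid_size(al$coords[, , 1]), 1, tolerance = 1e-9)
  expect_equal(al$centroid_sizes[["a"]], centroid_size(cfg))
})

test_that("alignment removes rotation, translation and scale", {
  set.seed(11)
  a <- matrix(rnorm(24), 8, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  b <- (a %*% rot) * 3.7 + matrix(rep(c(5, -2, 1), each = 8), 8, 3)
  al <- gpa_align(list(a = a, b = b))
  d <- procrustes_distance(al$coords[, , "a"], al$coords[, , "b"])
  expect_lt(d, 1e-9)
})

test_that("GPA is idempotent and every aligned shape has unit centroid size", {
  set.seed(5)
  base <- matrix(rnorm(30), 10, 3)
  configs <- lapply(1:4, function(i) base + matrix(rnorm(30, sd = 0.1), 10, 3))
  al <- gpa_align(configs)
  expect_true(all(abs(apply(al$coords, 3, centroid_size) - 1) < 1e-9))
  al2 <- gpa_align(al$coords)
  expect_lt(max(abs(al2$coords - al$coords)), 1e-9)
})

test_that("planar three-configuration alignment matches the brute-force oracle", {
  set.seed(3)
  base <- cbind(c(0, 2, 2.2, 0.5), c(0, 0.1, 1.4, 1.2), 0)
  configs <- list(
    base,
    base + cbind(matrix(rnorm(8, sd = 0.15), 4, 2), 0),
    base + cbind(matrix(rnorm(8, sd = 0.15), 4, 2), 0)
  )
  al <- gpa_align(configs, tol = 1e-14)
  m <- apply(al$coords, c(1, 2), mean)
  ss_pkg <- sum(vapply(1:3, function(i) sum((al$coords[, , i] - m)^2), numeric(1)))
  ss_oracle <- oracle_gpa_planar(configs)
  expect_equal(ss_pkg, ss_oracle, tolerance = 1e-5)
})

test_that("degenerate configurations are rejected", {
  expect_error(gpa_align(list(matrix(0, 5, 3))), class = "shaperate_geometry")
  expect_error(gpa_align(list(matrix(rnorm(6), 2, 3))), class = "shaperate_geometry")
})

test_that("procrustes distance: identity, 3-4-5, loop oracle, dimension error", {
  expect_equal(procrustes_distance(1:6, 1:6), 0)
  a <- rep(0, 9); b <- a; b[4:6] <- c(3, 4, 0)
  expect_equal(procrustes_distance(a, b), 5)
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(procrustes_distance(x, y), oracle_distance_loop(x, y),
               tolerance = 1e-12)
  expect_error(procrustes_distance(1:6, 1:9), class = "shaperate_dimension")
})

test_that("consensus uses the subspecies grand mean, not the pooled mean", {
  # one subspecies with 1 specimen at 0, another with 3 specimens at 2:
  # grand mean 1.0, pooled mean 1.5
  k <- 3
  mk <- function(v) matrix(c(v, 0, 0, -v, 0, 0, 0, 1, 0), k, 3, byrow = TRUE)
  coords <- array(0, c(k, 3, 4), dimnames = list(NULL, NULL, paste0("s", 1:4)))
  vals <- c(0, 2, 2, 2)
  for (i in 1:4) coords[, , i] <- mk(vals[i])
  meta <- tibble::tibble(
    specimen = paste0("s", 1:4), species = "sp", sex = "male",
    subspecies = c("u1", "u2", "u2", "u2")
  )
  aligned <- structure(list(coords = coords, centroid_sizes = rep(1, 4),
                            mean_shape = mk(1), specimens = meta, regions = NULL),
                       class = "aligned_shapes")
  cons <- consensus_by_species_sex(aligned, meta)
  expect_equal(cons$shape[[1]], flatten_config_test(mk(1)))
})

test_that("consensus is permutation invariant and identical shapes give themselves", {
  sim <- cached_fixture("null")
  ds <- sim$dataset
  al <- gpa_align(ds)
  cons <- consensus_by_species_sex(al)
  expect_equal(nrow(cons), 32) # 16 species x 2 sexes
  perm <- sample(n_specimens(ds))
  ds2 <- landmark_dataset(ds$coords[, , perm], ds$specimens[perm, ], ds$regions)
  al2 <- al
  al2$coords <- al$coords[, , perm]
  al2$centroid_sizes <- al$centroid_sizes[perm]
  al2$specimens <- ds$specimens[perm, ]
  cons2 <- consensus_by_species_sex(al2)
  expect_equal(cons, cons2)
})
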