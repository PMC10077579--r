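two_blob_dist <- function(n_per = 5, within = 0.01, between = 0.9) {
  n <- 2 * n_per
  m <- matrix(between, n, n)
  m[1:n_per, 1:n_per] <- within
  m[(n_per + 1):n, (n_per + 1):n] <- within
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  stats::as.dist(m)
}

test_that("silhouette maximisation recovers two well-separated blobs", {
  d <- two_blob_dist()
  cl <- hierarchical_cluster(d, k_range = 2:8)
  expect_equal(cl$k, 2)
  expect_equal(unname(table(cl$labels)), c(5L, 5L), ignore_attr = TRUE)
  expect_true(all(cl$silhouette >= -1 & cl$silhouette <= 1))
  expect_gt(cl$mean_silhouette, 0.9)
  # deterministic
  expect_identical(cl$labels, hierarchical_cluster(d, k_range = 2:8)$labels)
})

test_that("flat distance matrices fall back to the smallest k with a warning", {
  m <- matrix(0.5, 6, 6)
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  d <- stats::as.dist(m)
  expect_warning(cl <- hierarchical_cluster(d, k_range = 2:4), "flat")
  expect_equal(cl$k, 2)
  expect_error(hierarchical_cluster(d, k_range = 2:10), "k_range")
})

test_that("dendrograms can be written as Newick trees", {
  d <- two_blob_dist()
  cl <- hierarchical_cluster(d)
  tmp <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, attr(d, "Labels"))
})

test_that("NMDS embeds line-like distances with near-zero stress, reproducibly", {
  x <- seq(0, 1, length.out = 8)
  d <- stats::dist(cbind(x, 0))
  attr(d, "Labels") <- paste0("s", 1:8)
  o1 <- suppressWarnings(nmds_ordination(d, seed = 5))
  o2 <- suppressWarnings(nmds_ordination(d, seed = 5))
  expect_lt(o1$stress, 0.01)
  expect_equal(o1$points, o2$points)
})

test_that("post-hoc vector fitting recovers a variable aligned with an axis", {
  set.seed(501)
  pts <- cbind(rnorm(20), rnorm(20))
  ord <- structure(list(points = pts, stress = 0.01), class = "nmds_ordination")
  env <- data.frame(aligned = pts[, 1], noise = rnorm(20))
  fit <- fit_env_vectors(ord, env, c("aligned", "noise"), n_perm = 199, seed = 1)
  expect_equal(fit$r2[fit$variable == "aligned"], 1, tolerance = 1e-6)
  expect_equal(fit$p[fit$variable == "aligned"], 1 / 200)
  # reversing the sign keeps r2, flips the direction
  env2 <- data.frame(aligned = -pts[, 1])
  fit2 <- fit_env_vectors(ord, env2, "aligned", n_perm = 199, seed = 1)
  expect_equal(fit2$r2, 1, tolerance = 1e-6)
  expect_equal(fit2$axis1, -fit$axis1[fit$variable == "aligned"], tolerance = 1e-6)
  expect_error(
    fit_env_vectors(ord, data.frame(const = rep(1, 20)), "const"),
    "constant"
  )
  expect_error(fit_env_vectors(ord, env, "absent"), "absent")
})

test_that("IndVal reproduces hand arithmetic and its analytic maximum", {
  # formula in every sample of cluster 1 and nowhere else -> IndVal 1
  m <- rbind(
    a1 = c(1, 0.2), a2 = c(1, 0.5), a3 = c(1, 0.1),
    b1 = c(0, 0.4), b2 = c(0, 0.3), b3 = c(0, 0.2)
  )
  colnames(m) <- c("exclusive", "shared")
  cl <- c(a1 = 1, a2 = 1, a3 = 1, b1 = 2, b2 = 2, b3 = 2)
  res <- indval(m, cl, n_perm = 199, seed = 1)
  expect_equal(res$indval[res$formula == "exclusive"], 1)
  expect_equal(res$A[res$formula == "exclusive"], 1)
  expect_equal(res$B[res$formula == "exclusive"], 1)
  # mean abundance 3 vs 1, present in half of cluster-1 samples:
  # A = 3/4, B = 1/2, IndVal = 0.375
  m2 <- cbind(f = c(6, 6, 0, 0, 1, 1, 1, 1))
  rownames(m2) <- paste0("s", 1:8)
  cl2 <- rep(1:2, each = 4)
  res2 <- indval(m2, cl2, n_perm = 199, seed = 1)
  expect_equal(res2$A, 0.75)
  expect_equal(res2$B, 0.5)
  expect_equal(res2$indval, 0.375)
  expect_equal(res2$best_cluster, 1L)
})

test_that("IndVal p-values are valid permutation p-values with BH adjustment", {
  set.seed(502)
  m <- matrix(runif(8 * 30), 8, 30)
  rownames(m) <- paste0("s", 1:8)
  colnames(m) <- paste0("f", 1:30)
  cl <- rep(1:2, each = 4)
  res <- indval(m, cl, n_perm = 99, seed = 3)
  expect_true(all(res$indval >= 0 & res$indval <= 1))
  expect_true(all(res$p_raw >= 1 / 100))
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_error(indval(m, c(1, rep(2, 7)), n_perm = 9), "singleton")
  expect_error(indval(m, rep(1, 8), n_perm = 9), "2 clusters")
})

test_that("Mantel statistic is 1 for identical or affinely related matrices", {
  set.seed(503)
  pts <- matrix(rnorm(20), 10, 2)
  d1 <- stats::dist(pts)
  attr(d1, "Labels") <- paste0("s", 1:10)
  r_self <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(r_self$r, 1)
  d2 <- 3 * d1 + 0.2
  r_aff <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  expect_equal(r_aff$r, 1)
  expect_lte(r_aff$p, 0.05)
  d3 <- d1
  attr(d3, "Labels") <- paste0("x", 1:10)
  expect_error(mantel_test(d1, d3, n_perm = 9), "different samples")
})

test_that("great-circle distances match the spherical-arc hand value", {
  env <- data.frame(
    lake_id = c("o", "e"), latitude = c(0, 0), longitude = c(0, 1)
  )
  d <- haversine_matrix(env)
  # one degree of longitude at the equator: pi * 6371.0088 / 180
  expect_equal(as.vector(d), 111.1950793, tolerance = 1e-6)
  m <- as.matrix(d)
  expect_equal(m, t(m))
  same <- data.frame(lake_id = c("a", "b"), latitude = c(-69, -69), longitude = c(39, 39))
  expect_equal(as.vector(haversine_matrix(same)), 0)
  bad <- data.frame(lake_id = "a", latitude = 100, longitude = 0)
  expect_error(haversine_matrix(bad), "coordinates")
})

test_that("environmental distances are z-scored and affine-invariant", {
  env <- data.frame(
    lake_id = c("a", "b", "c"),
    EC = c(0.01, 0.1, 10), pH = c(7.2, 7.8, 8.6),
    water_temperature = c(1, 3, 6), DIN = c(2, 4, 30)
  )
  d <- env_distance(env)
  # rescaling any variable leaves z-scores unchanged
  env2 <- env
  env2$pH <- env2$pH * 13 + 5
  env2$DIN <- env2$DIN * 0.001
  expect_equal(as.vector(env_distance(env2)), as.vector(d), tolerance = 1e-12)
  # duplicated samples are at distance zero
  env3 <- rbind(env, env[1, ])
  env3$lake_id <- c("a", "b", "c", "a2")
  m3 <- as.matrix(env_distance(env3))
  expect_equal(m3["a", "a2"], 0)
  expect_error(
    env_distance(data.frame(lake_id = 1:3, EC = c(1, 2, 3), pH = 7,
      water_temperature = c(1, 2, 3), DIN = c(1, 2, 3))),
    "zero-variance"
  )
  # one variable, two samples: distance is |z1 - z2| = sqrt(2) for n = 2
  env4 <- data.frame(lake_id = c("a", "b"), EC = c(1, 10))
  expect_equal(as.vector(env_distance(env4, vars = "EC")), sqrt(2), tolerance = 1e-12)
})

test_that("null calibration: Mantel p-values are approximately uniform under independence", {
  set.seed(504)
  reps <- 120
  pv <- replicate(reps, {
    d1 <- stats::dist(matrix(rnorm(16), 8, 2))
    d2 <- stats::dist(matrix(rnorm(16), 8, 2))
    mantel_test(d1, d2, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(pv <= 0.05), 0.0)
  expect_lt(mean(pv <= 0.05), 0.12)
  expect_lt(suppressWarnings(stats::ks.test(pv, "punif")$statistic), 0.15)
})
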