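test_that("richness counts distinct formulas once", {
  f <- molecular_formula(c(6, 6, 8), c(12, 12, 8), O = c(6, 6, 4))
  s <- make_assigned(f, c(1, 2, 3))
  expect_equal(richness(s), 2) # two peaks map to one formula
  s3 <- make_assigned(molecular_formula(c(6, 8, 9), c(12, 8, 10), O = c(6, 4, 4)), c(1, 1, 1))
  expect_equal(richness(s3), 3)
})

test_that("Gini-Simpson matches closed forms and a two-draw Monte-Carlo estimate", {
  expect_equal(gini_simpson(1), 0)
  expect_equal(gini_simpson(c(0.5, 0.5)), 0.5)
  for (n in c(4, 50)) {
    expect_equal(gini_simpson(rep(1 / n, n)), 1 - 1 / n)
  }
  expect_error(gini_simpson(c(0.5, 0.2)), "normalised")
  # probability that two sampled molecules differ
  set.seed(401)
  p <- runif(20)
  p <- p / sum(p)
  draws1 <- sample.int(20, 1e5, replace = TRUE, prob = p)
  draws2 <- sample.int(20, 1e5, replace = TRUE, prob = p)
  expect_equal(gini_simpson(p), mean(draws1 != draws2), tolerance = 0.01)
})

test_that("Rao functional diversity equals the naive double sum and scales linearly", {
  expect_equal(functional_diversity(1, 5), 0)
  expect_equal(functional_diversity(c(0.5, 0.5), c(1, 3)), 1)
  expect_equal(functional_diversity(c(0.3, 0.7), c(2, 2)), 0)
  set.seed(402)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    p <- runif(n)
    p <- p / sum(p)
    x <- rnorm(n, sd = 10)
    expect_equal(functional_diversity(p, x), naive_rao(p, x), tolerance = 1e-12)
    expect_equal(functional_diversity(p, 3 * x), 3 * functional_diversity(p, x))
  }
  expect_error(functional_diversity(c(0.5, 0.5), 1), "length")
})

test_that("binned DBE_AI distributions count distinct formulas and ignore intensity", {
  # four formulas hand-picked to have DBE_AI {2, 2, 2.5, 3}:
  # C10H12O6 -> 1+10-3-6, C11H13O6N1 -> 1+11-3-7,
  # C11H12O7 -> 1+11-3.5-6, C11H12O6 -> 1+11-3-6
  f <- molecular_formula(
    C = c(10, 11, 11, 11), H = c(12, 13, 12, 12),
    O = c(6, 6, 7, 6), N = c(0, 1, 0, 0)
  )
  expect_equal(dbe_ai(f), c(2, 2, 2.5, 3))
  s <- make_assigned(f, c(10, 1, 1, 1))
  bd <- binned_distribution(s)
  expect_equal(bd$bin_centers, c(2, 2.5, 3))
  expect_equal(bd$probabilities, c(0.5, 0.25, 0.25))
  # intensity scaling leaves the distribution unchanged
  s10 <- make_assigned(f, 10 * c(10, 1, 1, 1))
  expect_equal(binned_distribution(s10), bd)
  # single-bin degenerate case
  s1 <- make_assigned(f[1:2, ], c(1, 1))
  bd1 <- binned_distribution(s1)
  expect_equal(bd1$probabilities, 1)
})

test_that("Jensen-Shannon divergence matches the hand example and its bounds", {
  expect_equal(jensen_shannon(c(1, 0), c(0.5, 0.5)), 0.311278, tolerance = 1e-4)
  expect_equal(jensen_shannon(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # disjoint supports reach the base-2 upper bound exactly
  expect_equal(jensen_shannon(c(1, 0), c(0, 1)), 1)
  set.seed(403)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    p <- runif(n)
    p <- p / sum(p)
    q <- runif(n)
    q <- q / sum(q)
    v <- jensen_shannon(p, q)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, jensen_shannon(q, p), tolerance = 1e-12)
  }
  expect_error(jensen_shannon(c(0.5, 0.2), c(0.5, 0.5)), "normalised")
})

test_that("distribution objects align on the union of supports for JSd", {
  pd <- structure(list(bin_centers = c(1, 1.5), probabilities = c(0.5, 0.5)),
    class = "binned_distribution"
  )
  qd <- structure(list(bin_centers = c(1.5, 2), probabilities = c(0.5, 0.5)),
    class = "binned_distribution"
  )
  v <- jensen_shannon(pd, qd)
  expect_equal(v, jensen_shannon(c(0.5, 0.5, 0), c(0, 0.5, 0.5)))
})

test_that("Bray-Curtis matches hand arithmetic and distance invariants", {
  m <- rbind(a = c(0.6, 0.4, 0), b = c(0.2, 0.4, 0.4))
  colnames(m) <- paste0("f", 1:3)
  d <- bray_curtis_matrix(m)
  expect_equal(as.vector(d), 0.4)
  # identical rows -> 0; disjoint -> 1
  m2 <- rbind(a = c(0.5, 0.5, 0, 0), b = c(0.5, 0.5, 0, 0), c = c(0, 0, 0.5, 0.5))
  colnames(m2) <- paste0("f", 1:4)
  d2 <- as.matrix(bray_curtis_matrix(m2))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  # invariance to column order
  perm <- c(3, 1, 2)
  expect_equal(as.vector(bray_curtis_matrix(m[, perm])), 0.4)
  expect_error(bray_curtis_matrix(rbind(a = c(1, 1), b = c(0, 0))), "zero")
})

test_that("JSd matrices are symmetric, zero-diagonal, bin-order invariant", {
  set.seed(404)
  f <- molecular_formula(
    C = sample(8:20, 30, TRUE), H = sample(8:30, 30, TRUE),
    O = sample(1:8, 30, TRUE), N = sample(0:2, 30, TRUE)
  )
  f <- f[!duplicated(formula_string(f)), ]
  samples <- lapply(1:4, function(i) {
    keep <- sample(nrow(f), 15)
    make_assigned(f[keep, ], runif(15), paste0("s", i))
  })
  d <- jsd_matrix(samples)
  m <- as.matrix(d)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  # permuting the sample list permutes the matrix consistently
  d2 <- jsd_matrix(samples[c(3, 1, 2, 4)])
  expect_equal(as.matrix(d2)[rownames(m), colnames(m)], m)
})

test_that("alpha diversity table carries richness, Gini-Simpson and six Rao columns", {
  set.seed(405)
  f <- molecular_formula(
    C = sample(8:20, 25, TRUE), H = sample(8:30, 25, TRUE),
    O = sample(1:8, 25, TRUE), N = sample(0:2, 25, TRUE)
  )
  f <- f[!duplicated(formula_string(f)), ]
  s1 <- make_assigned(f, runif(nrow(f)), "s1")
  s2 <- make_assigned(f[1:5, ], runif(5), "s2")
  tab <- alpha_diversity(list(s1, s2))
  expect_equal(tab$sample_id, c("s1", "s2"))
  expect_equal(tab$D_R, c(nrow(f), 5))
  expect_true(all(tab$D_A >= 0 & tab$D_A <= 1))
  expect_true(all(c("D_F_C", "D_F_HC", "D_F_NC", "D_F_AImod", "D_F_DBE", "D_F_NOSC")
  %in% names(tab)))
  # Rao on one sample agrees with direct computation on carbon number
  ints <- s2$assignments$intensity
  p <- ints / sum(ints)
  expect_equal(tab$D_F_C[2], naive_rao(p, f$C[1:5]), tolerance = 1e-12)
})
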