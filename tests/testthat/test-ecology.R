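test_that("alpha diversity indices match their closed forms", {
  expect_equal(shannon(rep(0.25, 4)), log(4), tolerance = 1e-10)
  expect_equal(shannon(c(1, 0, 0)), 0, tolerance = 1e-10)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)

  expect_equal(inverse_simpson(rep(1 / 7, 7)), 7, tolerance = 1e-10)
  expect_equal(inverse_simpson(c(1, 0)), 1, tolerance = 1e-10)
  expect_equal(inverse_simpson(c(0.5, 0.25, 0.25)), 1 / 0.375, tolerance = 1e-10)

  expect_error(shannon(c(-0.1, 1.1)), "non-negative")
  expect_error(inverse_simpson(c(0.3, 0.3)), "sum to 1")

  # both indices are maximal at uniformity
  k <- 5
  unif <- rep(1 / k, k)
  pert <- unif + c(0.03, -0.03, 0, 0, 0)
  expect_gt(shannon(unif), shannon(pert))
  expect_gt(inverse_simpson(unif), inverse_simpson(pert))
})

test_that("the rank test enumerates exactly for small samples and matches Kruskal-Wallis", {
  # complete separation: zero (a > b) pairs
  expect_equal(rank_test_two_groups(c(1, 2, 3), c(4, 5, 6))$U, 0)

  # interleaved toy: exact p from brute-force enumeration of all 20 splits
  a <- c(1, 3, 5); b <- c(2, 4, 6)
  res <- rank_test_two_groups(a, b)
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">"))
  null_u <- apply(utils::combn(6, 3), 2, function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">"))
  })
  # two-sided exact p: probability of a U at least as extreme as observed
  p_exact <- mean(abs(null_u - 4.5) >= abs(u_obs - 4.5))
  expect_equal(res$U, u_obs)
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)
  expect_gt(res$p_value, 0.5)

  # two-group Kruskal-Wallis and Mann-Whitney agree (tie-free, normal approx)
  set.seed(8)
  x <- rnorm(15); y <- rnorm(17)
  p_mw <- rank_test_two_groups(x, y)$p_value
  p_kw <- kruskal.test(list(x, y))$p.value
  expect_equal(p_mw, p_kw, tolerance = 1e-9)
})

test_that("alpha diversity report tests both indices between statuses", {
  ds <- generate_dataset(sim_config(n_genera = 30, seed = 3))
  rep_ <- alpha_diversity(ds$counts, ds$metadata)
  expect_equal(nrow(rep_$samples), 12)
  expect_true(all(rep_$samples$shannon >= 0))
  expect_true(all(rep_$samples$inverse_simpson >= 1))
  expect_equal(rep_$tests$index, c("shannon", "inverse_simpson"))
  expect_true(all(rep_$tests$p_value >= 0 & rep_$tests$p_value <= 1))
  expect_identical(tidy(rep_), rep_$samples)
  expect_identical(glance(rep_), rep_$tests)
})

test_that("Bray-Curtis follows its closed form", {
  m <- rbind(a = c(1, 1), b = c(1, 0), c = c(0, 2))
  bc <- bray_curtis(m)
  expect_equal(bc["a", "b"], 1 / 3, tolerance = 1e-10)
  expect_equal(bc["b", "c"], 1, tolerance = 1e-10) # disjoint supports
  expect_equal(unname(diag(bc)), c(0, 0, 0))
  expect_equal(bc, t(bc))
  expect_equal(bray_curtis(rbind(x = c(2, 3), y = c(2, 3)))["x", "y"], 0)
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("NMDS recovers a planar configuration almost perfectly", {
  set.seed(14)
  pts <- matrix(rnorm(30 * 2), 30, 2)
  rownames(pts) <- sprintf("s%d", 1:30)
  d <- as.matrix(dist(pts))
  ord <- suppressWarnings(nmds(d, restarts = 5, seed = 5))
  expect_lt(ord$stress, 0.01)
  co <- as.matrix(ord$coordinates[, c("NMDS1", "NMDS2")])
  expect_gt(procrustes_correlation(co, pts), 0.99)
  # determinism under a fixed seed
  ord2 <- suppressWarnings(nmds(d, restarts = 5, seed = 5))
  expect_equal(ord$coordinates, ord2$coordinates)
  expect_equal(ord$stress, ord2$stress)
})

test_that("PERMANOVA pseudo-F matches the direct sum-of-squares oracle", {
  set.seed(6)
  n <- 16
  coords <- matrix(rnorm(n * 2), n, 2)
  status <- balanced_status(n)
  res <- permanova_on_axes(coords, status, n_permutations = 199, seed = 2)

  # classical one-way decomposition on the coordinates
  grand <- colMeans(coords)
  ssb <- 0; ssw <- 0
  for (l in unique(status)) {
    sub <- coords[status == l, , drop = FALSE]
    mu <- colMeans(sub)
    ssb <- ssb + nrow(sub) * sum((mu - grand)^2)
    ssw <- ssw + sum(sweep(sub, 2, mu)^2)
  }
  f_oracle <- (ssb / 1) / (ssw / (n - 2))
  expect_equal(res$pseudo_F, f_oracle, tolerance = 1e-8)

  # p is invariant to rotating / translating the coordinates
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  res_rot <- permanova_on_axes(coords %*% rot + 5, status,
                               n_permutations = 199, seed = 2)
  expect_equal(res_rot$pseudo_F, res$pseudo_F, tolerance = 1e-8)
  expect_equal(res_rot$p_value, res$p_value)

  # extreme separation reaches the smallest attainable p
  sep <- coords; sep[status == "HHS", 1] <- sep[status == "HHS", 1] + 100
  res_sep <- permanova_on_axes(sep, status, n_permutations = 199, seed = 3)
  expect_equal(res_sep$p_value, 1 / 200)
})

test_that("beta diversity bundles dissimilarity, ordination and the group test", {
  ds <- generate_dataset(sim_config(n_genera = 30, n_differential = 8,
                                    effect_size = 3, seed = 19))
  bd <- suppressWarnings(
    beta_diversity(ds$counts, ds$metadata, restarts = 5,
                   n_permutations = 199, seed = 4)
  )
  expect_true(all(bd$dissimilarity >= 0 & bd$dissimilarity <= 1))
  expect_true("status" %in% names(bd$ordination$coordinates))
  expect_equal(glance(bd)$p_value, bd$permanova$p_value)
  # strong injected signal separates the groups
  expect_lt(bd$permanova$p_value, 0.05)

  bd_alr <- suppressWarnings(
    beta_diversity(ds$counts, ds$metadata, beta_on = "alr_euclidean",
                   alr = preprocess(ds$counts, ds$metadata)$alr,
                   restarts = 5, n_permutations = 199, seed = 4)
  )
  expect_s3_class(bd_alr, "beta_diversity")
})
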