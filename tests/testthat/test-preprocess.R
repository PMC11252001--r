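test_that("sparsity filter applies the within-status 25% rule to both groups", {
  # 6 + 6 samples: 2 zeros in one status = 33.3% -> excluded;
  # 1 zero in each status = 16.7% -> retained; 3/6 in LHS -> excluded
  counts <- toy_counts(zeros = list(
    g02 = c(1, 2),       # two zeros among HHS
    g03 = c(3, 9),       # one zero in each status
    g04 = c(7, 8, 10)    # three zeros among LHS
  ))
  meta <- toy_metadata(counts)
  out <- filter_sparse_genera(counts, meta)
  expect_identical(names(out), c("sample_id", "g01", "g03"))
  expect_identical(out$sample_id, counts$sample_id)

  # idempotent
  expect_identical(filter_sparse_genera(out, meta), out)

  # all-excluded is a hard error with per-genus diagnostics
  allz <- toy_counts(zeros = list(g01 = 1:3, g02 = 1:3, g03 = 1:3, g04 = 1:3))
  allz$g01[4] <- 1 # keep row sums positive
  expect_error(filter_sparse_genera(allz, meta), "all genera excluded")
})

test_that("zero replacement follows the stated conventions exactly", {
  nz <- toy_counts()
  expect_equal(replace_zeros(nz, "pseudocount_one"), nz, ignore_attr = TRUE)
  expect_equal(replace_zeros(nz, "half_minimum"), nz, ignore_attr = TRUE)

  col <- tibble::tibble(sample_id = c("a", "b", "c"), g1 = c(0, 4, 8),
                        g2 = c(5, 5, 5))
  expect_equal(replace_zeros(col, "half_minimum")$g1, c(2, 4, 8))

  col2 <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         g1 = c(0, 3, 0, 5), g2 = c(1, 1, 1, 1))
  expect_equal(replace_zeros(col2, "pseudocount_one")$g1, c(1, 3, 1, 5))

  allzero <- tibble::tibble(sample_id = c("a", "b"), g1 = c(0, 0), g2 = c(1, 2))
  expect_error(replace_zeros(allzero), "all-zero")
})

test_that("ALR reference minimises the CV of relative abundance", {
  # constant relative abundances -> CV 0 for every genus, tie broken by id
  rel_const <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    g1 = c(10, 30, 5), g2 = c(20, 60, 10), g3 = c(10, 30, 5)
  ) # shares are 25/50/25 in every sample
  expect_identical(select_alr_reference(rel_const), "g1")

  # hand-computed CVs on a 3-sample toy
  toy <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    g1 = c(0.30, 0.33, 0.36), g2 = c(0.70, 0.67, 0.64)
  )
  cv1 <- sd(c(.30, .33, .36)) / mean(c(.30, .33, .36)) # 0.0909
  cv2 <- sd(c(.70, .67, .64)) / mean(c(.70, .67, .64)) # 0.0448
  expect_lt(cv2, cv1)
  expect_identical(select_alr_reference(toy), "g2")

  expect_error(select_alr_reference(toy[, 1:2]), "at least 2")
})

test_that("ALR transform matches its closed form and is closure-invariant", {
  toy <- tibble::tibble(sample_id = "s1", g1 = 2, g2 = 4, g3 = 1)
  alr <- alr_transform(toy, "g3")
  expect_equal(unlist(alr[1, c("g1", "g2")]), c(g1 = log(2), g2 = log(4)))
  expect_identical(attr(alr, "reference"), "g3")

  # x_j = x_ref -> zero column
  eqcol <- tibble::tibble(sample_id = c("a", "b"), g1 = c(3, 7), g2 = c(3, 7))
  expect_equal(alr_transform(eqcol, "g2")$g1, c(0, 0))

  # multiplying a sample's row by any constant leaves the ALR unchanged
  set.seed(4)
  m <- matrix(rexp(5 * 6) + 0.1, 5, 6,
              dimnames = list(sprintf("s%d", 1:5), sprintf("g%d", 1:6)))
  tb <- tibble::as_tibble(m, rownames = "sample_id")
  scaled_tb <- tb
  scaled_tb[3, -1] <- tb[3, -1] * 10
  expect_equal(alr_transform(tb, "g4"), alr_transform(scaled_tb, "g4"))

  expect_error(alr_transform(tibble::tibble(sample_id = "a", g1 = 0, g2 = 1), "g2"),
               "strictly positive")
})

test_that("Procrustes correlation removes similarity transforms and matches an SVD oracle", {
  set.seed(20)
  x <- matrix(rnorm(20 * 5), 20, 5)
  expect_equal(procrustes_correlation(x, x), 1, tolerance = 1e-10)

  # rotated + uniformly scaled + translated copy -> still 1
  rot <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  y <- 3.7 * x %*% rot + matrix(rep(rnorm(5), each = 20), 20, 5)
  expect_equal(procrustes_correlation(x, y), 1, tolerance = 1e-8)

  # two independent Gaussian configurations vs brute-force SVD oracle
  z <- matrix(rnorm(20 * 5), 20, 5)
  expect_equal(procrustes_correlation(x, z), oracle_procrustes_corr(x, z),
               tolerance = 1e-8)
  # symmetric in its arguments
  expect_equal(procrustes_correlation(x, z), procrustes_correlation(z, x),
               tolerance = 1e-10)
})

test_that("autoscaling yields exact zero means and unit sample SDs", {
  tb <- tibble::tibble(sample_id = c("a", "b", "c"), g1 = c(1, 2, 3),
                       g2 = c(5, 1, 0))
  out <- autoscale(tb)
  expect_equal(out$values$g1, c(-1, 0, 1)) # sample SD convention
  m <- as.matrix(out$values[, -1])
  expect_true(all(abs(colMeans(m)) < 1e-10))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))
  expect_equal(out$scaling$mean, c(2, 2))

  # already-scaled column passes through with mean 0 / SD 1 recorded
  pre <- tibble::tibble(sample_id = c("a", "b", "c"), g1 = c(-1, 0, 1))
  out2 <- autoscale(pre)
  expect_equal(out2$values$g1, pre$g1)
  expect_equal(out2$scaling$sd, 1)

  flat <- tibble::tibble(sample_id = c("a", "b"), g1 = c(2, 2), g2 = c(1, 3))
  expect_error(autoscale(flat), "g1")
})

test_that("the preprocessing chain is ordered and self-consistent", {
  ds <- generate_dataset(sim_config(n_genera = 40, n_differential = 5,
                                    effect_size = 1.5, seed = 13))
  pp <- preprocess(ds$counts, ds$metadata)
  # retained genus count equals PLS-DA columns plus the reference
  expect_equal(pp$n_retained, ncol(pp$scaled) - 1 + 1)
  expect_false(pp$reference %in% names(pp$scaled))
  expect_true(pp$reference %in% names(pp$filtered_counts))
  expect_true(pp$procrustes_r > 0 && pp$procrustes_r <= 1)
  m <- as.matrix(pp$scaled[, -1])
  expect_true(all(abs(colMeans(m)) < 1e-10))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))
})
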