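cfg_fast <- function(seed = 1) mcmc_config(chains = 2, iterations = 3000,
                                           burn_in = 500, lag = 5, seed = seed)

test_that("the Gibbs sampler matches the analytic flat-prior posterior", {
  # With flat priors on both locations and log sigma, the marginal posterior
  # of the group difference is a scaled-and-shifted t: location = observed
  # mean difference, scale = s_p * sqrt(1/n1 + 1/n2), df = n - 2.
  status <- rep(c("HHS", "LHS"), each = 6)
  set.seed(100)
  y <- c(rnorm(6, 1, 0.5), rnorm(6, 0, 0.5))
  draws <- fit_single_effect(y, status, mcmc_config(seed = 1))

  dbar <- mean(y[1:6]) - mean(y[7:12])
  sp <- sqrt((sum((y[1:6] - mean(y[1:6]))^2) + sum((y[7:12] - mean(y[7:12]))^2)) / 10)
  scale_t <- sp * sqrt(1 / 3)

  n_draws <- length(draws)
  se_mean <- sd(draws) / sqrt(n_draws)
  expect_equal(mean(draws), dbar, tolerance = 1)
  expect_lt(abs(mean(draws) - dbar), 3 * se_mean)

  # posterior SD of the t-form (df = 10): scale * sqrt(df / (df - 2))
  expect_equal(sd(draws), scale_t * sqrt(10 / 8), tolerance = 0.05)

  # doubling iterations leaves the posterior mean stable
  draws2 <- fit_single_effect(y, status, mcmc_config(iterations = 10000, seed = 2))
  expect_lt(abs(mean(draws2) - mean(draws)),
            2 * (se_mean + sd(draws2) / sqrt(length(draws2))) + 1e-9)
})

test_that("a symmetric null gives a centred posterior and P0 near one half", {
  status <- rep(c("HHS", "LHS"), each = 5)
  y <- c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1) # identical group means and spreads
  draws <- fit_single_effect(y, status, cfg_fast())
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)))
  expect_lt(abs(p0(draws) - 0.5), 0.05
  )
  expect_error(fit_single_effect(c(1, 2, 3), c("HHS", "LHS", "LHS")), "at least 2")
})

test_that("HPD intervals are shortest contiguous mass intervals", {
  set.seed(7)
  z <- rnorm(10000)
  hpd <- hpd_interval(z, 0.95)
  expect_lt(abs(hpd[1] - (-1.96)), 0.05)
  expect_lt(abs(hpd[2] - 1.96), 0.05)
  # symmetric unimodal draws: HPD ~ equal-tailed interval
  expect_equal(hpd, unname(quantile(z, c(0.025, 0.975))), tolerance = 0.05)

  const <- rep(5, 200)
  expect_equal(hpd_interval(const), c(5, 5))

  expect_error(hpd_interval(z, 1.5), "mass")
  expect_error(hpd_interval(rnorm(10)), "100 draws")
})

test_that("P0 follows its sign-directed definition", {
  expect_equal(p0(c(0.5, 1, 2)), 1)
  set.seed(3)
  sym <- rnorm(20000)
  expect_lt(abs(p0(sym) - 0.5), 0.02)
  shifted <- rnorm(10000, mean = 1)
  expect_lt(abs(p0(shifted) - pnorm(1)), 0.02)
  # invariant under relabelling the groups (sign flip)
  expect_equal(p0(shifted), p0(-shifted))
})

test_that("per-genus summaries flag injected signal and keep input order", {
  n <- 12
  status <- balanced_status(n)
  set.seed(11)
  X <- scale(matrix(rnorm(n * 3), n, 3,
                    dimnames = list(sprintf("s%d", 1:n), c("null1", "big", "null2"))))
  X[, "big"] <- scale(ifelse(status == "HHS", 3, 0) + rnorm(n, sd = 0.3))
  out <- summarise_all(X, status, cfg_fast())
  expect_equal(out$genus_id, c("null1", "big", "null2"))
  expect_equal(nrow(out), 3)
  big <- out[out$genus_id == "big", ]
  expect_true(big$relevant)
  expect_gt(big$P0, 0.99)
  expect_true(all(out$hpd95_low <= out$hpd95_high))
  expect_true(all(out$P0 >= 0.45 & out$P0 <= 1))
  expect_equal(attr(out, "n_tested"), 3)

  fmt <- format_posterior_table(out)
  expect_match(fmt$P0[fmt$genus == "big"], "\\*$")
})

test_that("meanDiff is expressed in SD units of the variable", {
  n <- 12
  status <- balanced_status(n)
  set.seed(13)
  raw <- ifelse(status == "HHS", 1, 0) + rnorm(n, sd = 0.4)
  # rescaling the raw variable before autoscaling leaves meanDiff unchanged...
  tb1 <- tibble::tibble(sample_id = sprintf("s%d", 1:n), g = raw)
  tb2 <- tibble::tibble(sample_id = sprintf("s%d", 1:n), g = raw * 37)
  s1 <- summarise_all(autoscale(tb1)$values, status, cfg_fast())
  s2 <- summarise_all(autoscale(tb2)$values, status, cfg_fast())
  expect_equal(s1$meanDiff, s2$meanDiff, tolerance = 1e-10)
  # ...while on the raw scale the posterior difference scales with the data
  d1 <- fit_single_effect(raw, status, cfg_fast())
  d2 <- fit_single_effect(raw * 37, status, cfg_fast())
  expect_equal(mean(d2) / mean(d1), 37, tolerance = 0.05)
})

test_that("the null flagging rate of the P0 rule is modest", {
  # P0 > 0.95 corresponds to a mildly anti-conservative per-genus rule
  # (roughly a one-sided 5% tail); on null data the flagged fraction should
  # sit near 0.1, and far below half
  ds <- generate_dataset(sim_config(n_genera = 20, effect_size = 0, seed = 17))
  pp <- preprocess(ds$counts, ds$metadata)
  out <- summarise_all(pp$scaled, ds$metadata$status, cfg_fast())
  expect_lt(mean(out$relevant), 0.35)
})
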