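#' MCMC settings for the single-effect Bayesian model
#'
#' Defaults are a desk-scale profile (4 chains of 5,000 iterations); the
#' full-scale profile of 4 chains of 50,000 iterations, burn-in 1,000 and lag
#' 10 is available via `paper_scale = TRUE` or by setting the fields directly.
#'
#' @param chains Number of independent chains (default 4).
#' @param iterations Gibbs iterations per chain (default 5,000).
#' @param burn_in Discarded initial iterations per chain (default 1,000).
#' @param lag Thinning interval (default 10).
#' @param seed Integer seed; chains use distinct derived sub-seeds.
#' @param paper_scale If `TRUE`, use 50,000 iterations per chain.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iterations = 5000L, burn_in = 1000L,
                        lag = 10L, seed = 1L, paper_scale = FALSE) {
  if (paper_scale) iterations <- 50000L
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations")
  if (lag < 1) abort("lag must be at least 1")
  structure(
    list(chains = as.integer(chains), iterations = as.integer(iterations),
         burn_in = as.integer(burn_in), lag = as.integer(lag),
         seed = as.integer(seed)),
    class = "mcmc_config"
  )
}

# One Gibbs chain for y = mu + delta * I(HHS) + e, e ~ N(0, sigma^2), with
# improper flat priors on mu, delta and log sigma. All full conditionals are
# conjugate: normal for mu and delta, scaled inverse chi-square for sigma^2.
gibbs_chain <- function(y, h, config, chain_seed) {
  set.seed(chain_seed)
  n <- length(y)
  n1 <- sum(h)
  keep <- seq(config$burn_in + 1L, config$iterations, by = config$lag)
  draws <- numeric(length(keep))
  mu <- mean(y[h == 0])
  delta <- mean(y[h == 1]) - mu
  sigma2 <- var(y)
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  k <- 0L
  for (it in seq_len(config$iterations)) {
    r <- y - delta * h
    mu <- rnorm(1, mean(r), sqrt(sigma2 / n))
    z <- y - mu
    delta <- rnorm(1, mean(z[h == 1]), sqrt(sigma2 / n1))
    res <- y - mu - delta * h
    sigma2 <- sum(res^2) / rchisq(1, n)
    if (it > config$burn_in && (it - config$burn_in - 1L) %% config$lag == 0L) {
      k <- k + 1L
      draws[k] <- delta
    }
  }
  draws[seq_len(k)]
}

# Split-chain potential scale reduction factor on a draws matrix
# (columns = chains).
split_rhat <- function(draw_mat) {
  m <- nrow(draw_mat)
  half <- floor(m / 2)
  splits <- cbind(draw_mat[seq_len(half), , drop = FALSE],
                  draw_mat[(m - half + 1):m, , drop = FALSE])
  n <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior draws of the HHS - LHS difference for one variable
#'
#' Fits `y_i = mu + delta * I(status_i = HHS) + e_i`, `e ~ N(0, sigma^2)`,
#' with improper flat priors on `mu`, `delta` and `log sigma`, by Gibbs
#' sampling (all full conditionals are conjugate). Chains run independently
#' from distinct derived sub-seeds; draws after burn-in and thinning are
#' concatenated. A split-chain potential-scale-reduction factor above 1.01
#' raises a warning.
#'
#' When `values` are autoscaled (SD 1), the returned `delta` draws are already
#' expressed in SD units of the variable.
#'
#' @param values Numeric vector, one value per sample (e.g. one autoscaled
#'   ALR column).
#' @param status HHS/LHS labels aligned with `values`.
#' @param config An [mcmc_config()].
#' @return Numeric vector of posterior draws of `delta` (HHS - LHS).
#' @export
fit_single_effect <- function(values, status, config = mcmc_config()) {
  status <- as.character(status)
  stopifnot(length(values) == length(status), all(is.finite(values)))
  check_status(status)
  if (any(table(status) < 2)) {
    abort("each status group needs at least 2 samples for the variance to be identifiable")
  }
  h <- as.numeric(status == "HHS")
  per_chain <- lapply(seq_len(config$chains), function(ch) {
    gibbs_chain(values, h, config, derive_seed(config$seed, 7919L * ch))
  })
  len <- min(lengths(per_chain))
  if (config$chains > 1 && len >= 4) {
    rhat <- split_rhat(vapply(per_chain, function(d) d[seq_len(len)], numeric(len)))
    if (is.finite(rhat) && rhat > 1.01) {
      warn(sprintf("split-chain R-hat %.3f > 1.01: chains may not have converged", rhat))
    }
  }
  unlist(per_chain, use.names = FALSE)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the stated posterior mass, by the
#' sorted-draw sliding-window algorithm.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param mass Posterior mass in (0, 1) (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) abort("mass must be in (0, 1)")
  n <- length(draws)
  if (n < 100) abort("need at least 100 draws for an HPD interval")
  sorted <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(c(sorted[1], sorted[n]))
  widths <- sorted[(k + 1):n] - sorted[seq_len(n - k)]
  i <- which.min(widths)
  c(sorted[i], sorted[i + k])
}

#' Posterior probability that the difference exceeds zero in its own direction
#'
#' If the posterior mean of the draws is non-negative, returns the fraction of
#' draws above zero; otherwise the fraction below zero. By construction the
#' value lies in about \[0.5, 1\] and is invariant to relabelling the groups.
#'
#' @param draws Numeric vector of posterior draws.
#' @return Probability in \[0, 1\].
#' @export
p0 <- function(draws) {
  if (length(draws) == 0) abort("draws must be nonempty")
  if (mean(draws) >= 0) mean(draws > 0) else mean(draws < 0)
}

#' Per-genus Bayesian differential-abundance summaries
#'
#' Fits the flat-prior single-effect model to every column and reports, per
#' genus, the posterior mean of the HHS - LHS difference (`meanDiff`, in SD
#' units when the input is autoscaled), the 95% highest-posterior-density
#' interval, `P0`, and the relevance flag `P0 > 0.95`. No multiplicity
#' correction is applied; the number of genera tested is recorded as an
#' attribute `n_tested`.
#'
#' @param x Autoscaled values: tibble with `sample_id` plus genus columns
#'   (typically `preprocess()$scaled` restricted to the PLS-DA-selected
#'   genera), or a matrix.
#' @param status HHS/LHS labels aligned with the rows of `x`.
#' @param config An [mcmc_config()].
#' @return A tibble of class `posterior_summary` with columns `genus_id`,
#'   `hpd95_low`, `hpd95_high`, `meanDiff`, `P0`, `relevant`, in the input
#'   genus order.
#' @export
summarise_all <- function(x, status, config = mcmc_config()) {
  X <- as_X(x)
  status <- as.character(status)
  rows <- purrr::map(seq_len(ncol(X)), function(j) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 6007L * j)
    draws <- fit_single_effect(X[, j], status, cfg)
    hpd <- hpd_interval(draws, 0.95)
    prob <- p0(draws)
    tibble::tibble(
      genus_id = colnames(X)[j],
      hpd95_low = hpd[1], hpd95_high = hpd[2],
      meanDiff = mean(draws), P0 = prob, relevant = prob > 0.95
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_tested") <- ncol(X)
  class(out) <- c("posterior_summary", class(out))
  out
}

#' Format a posterior summary the way the abundance tables are printed
#'
#' @param summary A `posterior_summary` tibble.
#' @return A tibble with `HPD95` as a bracketed string and `P0` as a starred
#'   percentage (asterisk when relevant).
#' @export
format_posterior_table <- function(summary) {
  tibble::tibble(
    genus = summary$genus_id,
    HPD95 = sprintf("[%.2f, %.2f]", summary$hpd95_low, summary$hpd95_high),
    meanDiff = round(summary$meanDiff, 2),
    P0 = sprintf("%.2f%s", 100 * summary$P0, ifelse(summary$relevant, "*", ""))
  )
}
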