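# Shared fixtures and independent oracles, all built in code.

# Balanced 6 + 6 toy counts with controllable zero placement per genus.
# `zeros` is a named list: genus -> integer sample indices set to zero.
toy_counts <- function(zeros = list(), n_per_status = 6, n_genera = 4,
                       base = 100) {
  n <- 2 * n_per_status
  ids <- sprintf("s%02d", seq_len(n))
  m <- matrix(base + seq_len(n * n_genera) %% 7, n, n_genera,
              dimnames = list(ids, sprintf("g%02d", seq_len(n_genera))))
  for (g in names(zeros)) m[zeros[[g]], g] <- 0
  tibble::as_tibble(m, rownames = "sample_id")
}

toy_metadata <- function(counts, n_per_status = nrow(counts) / 2) {
  tibble::tibble(
    sample_id = counts$sample_id,
    status = rep(c("HHS", "LHS"), each = n_per_status),
    sample_type = "wall",
    farm_id = rep(sprintf("f%d", 1:6), length.out = nrow(counts))
  )
}

# Random column-standardised predictor matrix with balanced labels.
random_scaled_X <- function(n = 12, p = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", 1:p)))
  scale(X)[, , drop = FALSE]
}

balanced_status <- function(n) rep(c("HHS", "LHS"), each = n / 2)

# Independent Procrustes oracle: symmetric sum-of-squares correlation via a
# full SVD on centred, Frobenius-normalised configurations.
oracle_procrustes_corr <- function(x, y) {
  cx <- scale(x, scale = FALSE); cy <- scale(y, scale = FALSE)
  cx <- cx / sqrt(sum(cx^2)); cy <- cy / sqrt(sum(cy^2))
  d <- ncol(cx) - ncol(cy)
  if (d > 0) cy <- cbind(cy, matrix(0, nrow(cy), d))
  if (d < 0) cx <- cbind(cx, matrix(0, nrow(cx), -d))
  sum(svd(crossprod(cx, cy))$d)
}

# Brute-force PLS1 oracle: per deflation step the weight vector is the
# dominant eigenvector of Xa' y y' Xa; scores and deflation recomputed from
# scratch. Returns weights and scores for A components (columns sign-free).
oracle_pls <- function(X, y, A) {
  W <- matrix(0, ncol(X), A); Tm <- matrix(0, nrow(X), A)
  Xa <- X
  for (a in seq_len(A)) {
    M <- crossprod(Xa, y) %*% crossprod(y, Xa) # Xa' y y' Xa
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    t <- Xa %*% w
    p <- crossprod(Xa, t) / sum(t^2)
    Xa <- Xa - tcrossprod(t, p)
    W[, a] <- w; Tm[, a] <- t
  }
  list(weights = W, scores = Tm)
}

# Absolute column agreement up to sign.
max_abs_diff_up_to_sign <- function(a, b) {
  max(vapply(seq_len(ncol(a)), function(j) {
    min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
  }, numeric(1)))
}
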