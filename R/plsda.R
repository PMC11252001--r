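# Internal helpers shared by the PLS-DA routines. All hot-loop code works on
# plain matrices; the exported surface accepts `sample_id` tibbles as well.

as_X <- function(x) {
  if (is.data.frame(x)) counts_matrix(x) else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

# HHS -> +1, LHS -> -1. The design is balanced by construction, so the
# encoded vector is mean-zero and the single-column and dummy-matrix PLS-DA
# formulations coincide.
encode_status <- function(status) {
  check_status(status)
  ifelse(as.character(status) == "HHS", 1, -1)
}

# NIPALS-style PLS1 fit against the +/-1 encoding. X is expected to arrive
# column-standardised (see autoscale()); no re-centring happens here.
pls_core <- function(X, y_enc, A, strict = TRUE) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A); ss <- numeric(A)
  Xa <- X; ya <- y_enc
  achieved <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (strict) {
        abort(sprintf("no covariance left to extract at component %d; reduce n_components", a))
      }
      break
    }
    w <- w / nw
    t <- Xa %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) {
      if (strict) {
        abort(sprintf("degenerate score vector at component %d; reduce n_components", a))
      }
      break
    }
    pvec <- crossprod(Xa, t) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pvec)
    ya <- ya - t * qa
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t
    q[a] <- qa; ss[a] <- qa^2 * tt # class variance explained by component a
    achieved <- a
  }
  if (achieved < A) { # only reachable with strict = FALSE
    keep <- seq_len(max(achieved, 1L))
    W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]; ss <- ss[keep]
  }
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("comp", seq_len(ncol(W))))
  colnames(Tm) <- colnames(W)
  list(weights = W, x_loadings = P, y_loadings = q, scores = Tm, ss = ss)
}

# Projection matrix mapping raw (scaled) X into score space.
pls_rotation <- function(fit, a = ncol(fit$weights)) {
  W <- fit$weights[, seq_len(a), drop = FALSE]
  P <- fit$x_loadings[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W))
}

# Class centroids and pooled within-class covariance of the training scores.
score_geometry <- function(scores, status) {
  lev <- status_levels()
  centroids <- do.call(rbind, lapply(lev, function(l) {
    colMeans(scores[status == l, , drop = FALSE])
  }))
  rownames(centroids) <- lev
  a <- ncol(scores)
  pooled <- matrix(0, a, a)
  dfs <- 0
  for (l in lev) {
    s <- scores[status == l, , drop = FALSE]
    if (nrow(s) > 1) {
      pooled <- pooled + cov(s) * (nrow(s) - 1)
      dfs <- dfs + nrow(s) - 1
    }
  }
  pooled <- pooled / max(dfs, 1)
  list(centroids = centroids, cov = pooled)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least-squares fit of a column-standardised predictor matrix against
#' the sanitary-status encoding (HHS = +1, LHS = -1), by iterative
#' latent-variable extraction with deflation. The fitted object carries the
#' score-space geometry (class centroids and pooled within-class covariance)
#' needed for Mahalanobis classification.
#'
#' @param x Scaled predictors: a tibble with `sample_id` plus numeric genus
#'   columns (e.g. `preprocess()$scaled`) or a plain numeric matrix.
#' @param status Sanitary-status labels (HHS/LHS), one per sample.
#' @param n_components Number of latent components `A`; must not exceed the
#'   rank of `x`.
#' @return An object of class `plsda_model` with elements `weights`,
#'   `x_loadings`, `y_loadings`, `scores`, `ss` (per-component class variance
#'   explained), `centroids`, `cov`, `n_components`, `status`.
#' @examples
#' ds <- generate_dataset(sim_config(n_genera = 30, n_differential = 6,
#'                                   effect_size = 2, seed = 3))
#' pp <- preprocess(ds$counts, ds$metadata)
#' fit <- fit_plsda(pp$scaled, ds$metadata$status, n_components = 2)
#' @export
fit_plsda <- function(x, status, n_components = 2) {
  X <- as_X(x)
  status <- as.character(status)
  stopifnot(length(status) == nrow(X))
  y <- encode_status(status)
  A <- as.integer(n_components)
  if (A < 1) abort("n_components must be at least 1")
  r <- qr(X)$rank
  if (A > r) abort(sprintf("n_components (%d) exceeds rank of x (%d)", A, r))
  fit <- pls_core(X, y, A)
  geo <- score_geometry(fit$scores, status)
  structure(
    c(fit, geo, list(n_components = A, status = status,
                     variables = colnames(X))),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d samples, %d variables, %d component(s)\n",
              nrow(x$scores), length(x$variables), x$n_components))
  invisible(x)
}

mahalanobis_assign <- function(scores_new, centroids, covm) {
  a <- ncol(scores_new)
  inv <- tryCatch(solve(covm), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    # ridge fallback for singular pooled covariance
    eps <- 1e-8 * sum(diag(covm)) / a
    if (!is.finite(eps) || eps <= 0) eps <- 1e-8
    inv <- solve(covm + diag(eps, a))
    inform("singular score covariance: using ridge-regularised Mahalanobis distance")
  }
  lev <- rownames(centroids)
  d <- vapply(seq_len(nrow(centroids)), function(k) {
    diff <- sweep(scores_new, 2, centroids[k, ], "-")
    rowSums((diff %*% inv) * diff)
  }, numeric(nrow(scores_new)))
  d <- matrix(d, nrow = nrow(scores_new))
  # ties (equidistant points) resolve to the lexicographically smaller label,
  # which is first in status_levels() order
  lev[max.col(-d, ties.method = "first")]
}

#' Classify samples by Mahalanobis distance in PLS score space
#'
#' Projects new samples into the fitted model's latent-score space and assigns
#' each to the class whose centroid is nearest in Mahalanobis distance under
#' the pooled within-class score covariance. Exact ties resolve to the
#' lexicographically smaller class label (HHS).
#'
#' @param model A `plsda_model`.
#' @param x_new New samples on the same (scaled) variables as the training
#'   data; tibble or matrix.
#' @return Character vector of predicted status labels.
#' @export
classify_mahalanobis <- function(model, x_new) {
  stopifnot(inherits(model, "plsda_model"))
  X <- as_X(x_new)
  stopifnot(ncol(X) == length(model$variables))
  scores <- X %*% pls_rotation(model)
  mahalanobis_assign(scores, model$centroids, model$cov)
}

#' Variable importance in projection (VIP) scores
#'
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with unit-norm weight
#' vectors `w_a` and `SS_a` the class variance explained by component `a`.
#' The scores satisfy `sum_j VIP_j^2 = p`, so VIP = 1 is the "average
#' importance" line used as the pruning threshold.
#'
#' @param model A `plsda_model`.
#' @return Named numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W2 <- model$weights^2
  p <- nrow(W2)
  v <- sqrt(p * as.numeric(W2 %*% model$ss) / sum(model$ss))
  names(v) <- model$variables
  v
}
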