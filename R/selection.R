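# Cross-validated BER, the iterative VIP pruning loop, and the true/permuted
# confusion-matrix validation.

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so every training set contains both classes.
stratified_folds <- function(status, folds) {
  assignment <- integer(length(status))
  for (l in unique(status)) {
    idx <- which(status == l)
    if (length(idx) < folds) {
      abort(sprintf("class '%s' has %d samples, fewer than %d folds",
                    l, length(idx), folds))
    }
    assignment[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

# One pass of k-fold CV predictions at each of 1..A_max components.
# Returns a matrix n x A_max of predicted labels.
cv_predict_all_A <- function(X, status, y_enc, fold_of, folds, A_max) {
  n <- nrow(X)
  preds <- matrix(NA_character_, n, A_max)
  for (f in seq_len(folds)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    # non-strict: a rank-deficient training block caps the usable components
    fit <- pls_core(X[train, , drop = FALSE], y_enc[train], A_max, strict = FALSE)
    st_train <- status[train]
    A_eff <- ncol(fit$weights)
    for (a in seq_len(A_max)) {
      au <- min(a, A_eff)
      R <- pls_rotation(fit, au)
      geo <- score_geometry(fit$scores[, seq_len(au), drop = FALSE], st_train)
      preds[test, a] <- mahalanobis_assign(
        X[test, , drop = FALSE] %*% R, geo$centroids, geo$cov
      )
    }
  }
  preds
}

ber_from_preds <- function(pred, status) {
  mean(vapply(unique(status), function(l) {
    mean(pred[status == l] != l)
  }, numeric(1)))
}

default_A_max <- function(n, p, folds) {
  max(1L, min(p, n - ceiling(n / folds) - 1L, 5L))
}

#' Balanced error rate under repeated stratified k-fold cross-validation
#'
#' For each candidate number of components, runs `repetitions` rounds of
#' stratified k-fold cross-validation (fold assignment re-randomised each
#' round from the seeded generator), classifies held-out samples by
#' Mahalanobis distance, and averages the balanced error rate — the mean of
#' the two per-class error rates. Predictors are used as supplied: the
#' autoscaling fitted upstream is not refit per fold.
#'
#' @param x Scaled predictors (tibble with `sample_id`, or matrix).
#' @param status HHS/LHS labels.
#' @param folds Number of CV folds (default 4).
#' @param repetitions CV repetitions (default 100).
#' @param A_max Largest number of components searched; defaults to
#'   `min(p, smallest training size - 1, 5)`.
#' @param seed Integer seed for the fold randomisation.
#' @return A list of class `cv_ber`: `ber` (tibble `n_components`,
#'   `mean_ber`), `chosen_A` (argmin of mean BER; smallest `A` on ties),
#'   `folds`, `repetitions`.
#' @export
cv_ber <- function(x, status, folds = 4, repetitions = 100, A_max = NULL,
                   seed = 1L) {
  X <- as_X(x)
  status <- as.character(status)
  y <- encode_status(status)
  n <- nrow(X); p <- ncol(X)
  if (is.null(A_max)) A_max <- default_A_max(n, p, folds)
  A_max <- max(1L, as.integer(A_max))
  set.seed(seed)
  ber_sum <- numeric(A_max)
  for (r in seq_len(repetitions)) {
    fold_of <- stratified_folds(status, folds)
    preds <- cv_predict_all_A(X, status, y, fold_of, folds, A_max)
    for (a in seq_len(A_max)) {
      ber_sum[a] <- ber_sum[a] + ber_from_preds(preds[, a], status)
    }
  }
  mean_ber <- ber_sum / repetitions
  structure(
    list(
      ber = tibble::tibble(n_components = seq_len(A_max), mean_ber = mean_ber),
      chosen_A = which.min(mean_ber), # smallest A on ties
      folds = folds, repetitions = repetitions
    ),
    class = "cv_ber"
  )
}

#' @export
print.cv_ber <- function(x, ...) {
  cat(sprintf("<cv_ber> chosen A = %d (mean BER %.3f), %d-fold x %d reps\n",
              x$chosen_A, x$ber$mean_ber[x$chosen_A], x$folds, x$repetitions))
  invisible(x)
}

#' Iterative VIP-based variable selection for PLS-DA
#'
#' Repeats: choose the number of components by cross-validated balanced error
#' rate, fit on all samples, drop every variable with VIP below the threshold,
#' and refit on the survivors. The loop stops when no variable falls below the
#' threshold, when the cross-validated BER stops improving, or when fewer than
#' two variables would remain; the iteration with the lowest mean BER is
#' returned as final (the earliest such iteration on ties, so a BER tie never
#' forces extra pruning).
#'
#' @inheritParams cv_ber
#' @param vip_threshold Pruning threshold on the VIP score (default 1, the
#'   average-importance line).
#' @return An object of class `selection_trace`: `iterations` (tibble with
#'   `iteration`, `n_variables`, `n_components`, `mean_ber`, `variables`
#'   list-column), `final_selected` (genus ids), `final_model`
#'   (`plsda_model` refit on the selected set), `final_iteration`.
#' @export
iterative_vip_selection <- function(x, status, folds = 4, repetitions = 100,
                                    vip_threshold = 1, A_max = NULL,
                                    seed = 1L) {
  X <- as_X(x)
  status <- as.character(status)
  y <- encode_status(status)
  vars <- colnames(X)
  iters <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    Xi <- X[, vars, drop = FALSE]
    cv <- cv_ber(Xi, status, folds, repetitions, A_max,
                 seed = derive_seed(seed, it))
    A <- cv$chosen_A
    fit <- pls_core(Xi, y, A)
    geo <- score_geometry(fit$scores, status)
    model <- structure(
      c(fit, geo, list(n_components = A, status = status, variables = vars)),
      class = "plsda_model"
    )
    iters[[it]] <- list(
      iteration = it, n_variables = length(vars), n_components = A,
      mean_ber = cv$ber$mean_ber[A], variables = vars, model = model
    )
    if (it > 1 && iters[[it]]$mean_ber >= iters[[it - 1L]]$mean_ber) break
    vip <- vip_scores(model)
    keep <- vars[vip >= vip_threshold]
    if (length(keep) == length(vars)) break # nothing below threshold
    if (length(keep) < 2) break             # would leave < 2 variables
    vars <- keep
  }
  bers <- vapply(iters, `[[`, numeric(1), "mean_ber")
  best <- which.min(bers) # earliest iteration on ties: prune no further than needed
  structure(
    list(
      iterations = tibble::tibble(
        iteration = vapply(iters, `[[`, integer(1), "iteration"),
        n_variables = vapply(iters, `[[`, integer(1), "n_variables"),
        n_components = vapply(iters, `[[`, integer(1), "n_components"),
        mean_ber = bers,
        variables = lapply(iters, `[[`, "variables")
      ),
      final_selected = iters[[best]]$variables,
      final_model = iters[[best]]$model,
      final_iteration = best,
      vip_threshold = vip_threshold,
      folds = folds, repetitions = repetitions, seed = seed
    ),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "<selection_trace> %d iteration(s); final: %d variables, A = %d, mean BER %.3f\n",
    nrow(x$iterations), length(x$final_selected),
    x$iterations$n_components[x$final_iteration],
    x$iterations$mean_ber[x$final_iteration]
  ))
  invisible(x)
}

confusion_one_variant <- function(X, status, folds, repetitions, A, permute) {
  lev <- status_levels()
  conf <- matrix(0, 2, 2, dimnames = list(true = lev, predicted = lev))
  for (r in seq_len(repetitions)) {
    st <- if (permute) sample(status) else status
    y <- encode_status(st)
    fold_of <- stratified_folds(st, folds)
    preds <- cv_predict_all_A(X, st, y, fold_of, folds, A)[, A]
    for (i in seq_along(st)) {
      conf[st[i], preds[i]] <- conf[st[i], preds[i]] + 1
    }
  }
  pct <- conf / rowSums(conf) * 100
  structure(
    list(
      matrix = pct,
      true_positive_pct = stats::setNames(diag(pct), lev),
      variant = if (permute) "permuted" else "observed",
      folds = folds, repetitions = repetitions, n_components = A
    ),
    class = "confusion_summary"
  )
}

#' Observed and permuted confusion matrices for a PLS-DA variable set
#'
#' Validates a (typically VIP-selected) variable set by repeated stratified
#' k-fold cross-validation. The observed summary scores held-out predictions
#' against the true labels; the permuted summary shuffles the labels
#' independently before every repetition and scores predictions against the
#' shuffled labels, so its per-class true-positive rate should sit at the
#' two-class chance level of 50% — a model whose observed rates are far from
#' the permuted ones carries real, not selection-induced, signal.
#'
#' @inheritParams cv_ber
#' @param repetitions CV repetitions per variant (default 500; the
#'   full-scale choice of 10,000 is available by setting it explicitly).
#' @param A Number of components; chosen by [cv_ber()] when `NULL`.
#' @return A list of class `confusion_pair` with elements `observed` and
#'   `permuted`, each a `confusion_summary` (2x2 row-percentage matrix,
#'   per-class true-positive %, variant, folds, repetitions).
#' @export
confusion_matrices <- function(x, status, folds = 4, repetitions = 500,
                               A = NULL, seed = 1L) {
  X <- as_X(x)
  if (ncol(X) < 1) abort("selected variable set is empty")
  status <- as.character(status)
  if (is.null(A)) {
    A <- cv_ber(X, status, folds, repetitions = 100,
                seed = derive_seed(seed, 101L))$chosen_A
  }
  set.seed(derive_seed(seed, 202L))
  observed <- confusion_one_variant(X, status, folds, repetitions, A, permute = FALSE)
  set.seed(derive_seed(seed, 303L))
  permuted <- confusion_one_variant(X, status, folds, repetitions, A, permute = TRUE)
  structure(list(observed = observed, permuted = permuted),
            class = "confusion_pair")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> %s, %d-fold x %d reps, A = %d\n",
              x$variant, x$folds, x$repetitions, x$n_components))
  print(round(x$matrix, 1))
  invisible(x)
}

#' @export
print.confusion_pair <- function(x, ...) {
  print(x$observed); print(x$permuted)
  invisible(x)
}
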