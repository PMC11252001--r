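# broom-style tidiers for the fitted objects.

#' Tidy a PLS-DA model into one row per variable
#'
#' @param x A `plsda_model`.
#' @param ... Unused.
#' @return Tibble with `genus_id`, per-component weights and `vip`.
#' @method tidy plsda_model
#' @export
tidy.plsda_model <- function(x, ...) {
  W <- x$weights
  out <- tibble::as_tibble(W, rownames = "genus_id")
  names(out)[-1] <- paste0("weight_", colnames(W))
  out$vip <- unname(vip_scores(x))
  out
}

#' One-row summary of a PLS-DA model
#'
#' @inheritParams tidy.plsda_model
#' @return Tibble with `n_samples`, `n_variables`, `n_components`,
#'   `class_variance_explained` (sum of per-component SS).
#' @method glance plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_variables = length(x$variables),
    n_components = x$n_components,
    class_variance_explained = sum(x$ss)
  )
}

#' Tidy a selection trace into one row per pruning iteration
#'
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  dplyr::select(x$iterations, -"variables")
}

#' One-row summary of an iterative VIP selection
#'
#' @inheritParams tidy.selection_trace
#' @method glance selection_trace
#' @export
glance.selection_trace <- function(x, ...) {
  tibble::tibble(
    n_iterations = nrow(x$iterations),
    final_iteration = x$final_iteration,
    n_selected = length(x$final_selected),
    n_components = x$iterations$n_components[x$final_iteration],
    mean_ber = x$iterations$mean_ber[x$final_iteration]
  )
}

#' Tidy observed/permuted confusion summaries into long form
#'
#' @param x A `confusion_pair` or single `confusion_summary`.
#' @param ... Unused.
#' @return Tibble with `variant`, `true`, `predicted`, `pct`.
#' @method tidy confusion_pair
#' @export
tidy.confusion_pair <- function(x, ...) {
  dplyr::bind_rows(tidy(x$observed), tidy(x$permuted))
}

#' @rdname tidy.confusion_pair
#' @method tidy confusion_summary
#' @export
tidy.confusion_summary <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    variant = x$variant,
    true = rep(rownames(m), each = ncol(m)),
    predicted = rep(colnames(m), times = nrow(m)),
    pct = as.numeric(t(m))
  )
}

#' Per-sample tidy view of a diversity report
#'
#' @param x A `diversity_report`.
#' @param ... Unused.
#' @method tidy diversity_report
#' @export
tidy.diversity_report <- function(x, ...) x$samples

#' Test summary of a diversity report (one row per index)
#'
#' @inheritParams tidy.diversity_report
#' @method glance diversity_report
#' @export
glance.diversity_report <- function(x, ...) x$tests

#' Tidy beta-diversity ordination coordinates
#'
#' @param x A `beta_diversity`.
#' @param ... Unused.
#' @method tidy beta_diversity
#' @export
tidy.beta_diversity <- function(x, ...) x$ordination$coordinates

#' One-row beta-diversity summary (stress + PERMANOVA)
#'
#' @inheritParams tidy.beta_diversity
#' @method glance beta_diversity
#' @export
glance.beta_diversity <- function(x, ...) {
  dplyr::mutate(x$permanova, stress = x$ordination$stress, .before = 1)
}
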