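# ggplot2 methods for the result objects.

#' Ordination scatter plot
#'
#' @param object An `ordination_result` (e.g. from [nmds()]); points are
#'   coloured by `status` when that column is present in the coordinates.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ordination_result
#' @export
autoplot.ordination_result <- function(object, ...) {
  co <- object$coordinates
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  if ("status" %in% names(co)) {
    p <- p + ggplot2::aes(colour = .data$status)
  }
  p +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      title = "NMDS ordination",
      subtitle = sprintf("stress = %.3f", object$stress)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ordination_result
#' @method autoplot beta_diversity
#' @export
autoplot.beta_diversity <- function(object, ...) {
  autoplot(object$ordination, ...) +
    ggplot2::labs(caption = sprintf(
      "PERMANOVA on first two dimensions: F = %.2f, p = %.4f",
      object$permanova$pseudo_F, object$permanova$p_value
    ))
}

#' Balanced error rate across VIP pruning iterations
#'
#' @param object A `selection_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  it <- tidy(object)
  ggplot2::ggplot(it, ggplot2::aes(x = .data$iteration, y = .data$mean_ber)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_variables)) +
    ggplot2::geom_point(
      data = it[object$final_iteration, ],
      colour = "red", shape = 1, size = 6
    ) +
    ggplot2::scale_x_continuous(breaks = it$iteration) +
    ggplot2::labs(
      x = "pruning iteration", y = "mean cross-validated BER",
      size = "variables", title = "Iterative VIP selection"
    ) +
    ggplot2::theme_minimal()
}

#' Alpha-diversity boxplots by status
#'
#' @param object A `diversity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diversity_report
#' @export
autoplot.diversity_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$samples, c("shannon", "inverse_simpson"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$status, y = .data$value,
                                     fill = .data$status)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "diversity", title = "Alpha diversity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Forest plot of per-genus posterior summaries
#'
#' @param object A `posterior_summary` tibble from [summarise_all()].
#' @param ... Unused.
#' @return A ggplot: posterior mean difference (HHS - LHS, SD units) with the
#'   95% HPD interval per genus, relevant genera highlighted.
#' @method autoplot posterior_summary
#' @export
autoplot.posterior_summary <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$meanDiff)
  df$genus_id <- factor(df$genus_id, levels = df$genus_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$meanDiff, y = .data$genus_id,
                                   colour = .data$relevant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$hpd95_low, xmax = .data$hpd95_high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "posterior mean difference (HHS - LHS, SD units)", y = NULL,
      colour = "P0 > 0.95", title = "Bayesian differential abundance"
    ) +
    ggplot2::theme_minimal()
}
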