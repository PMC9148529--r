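# ggplot2 displays: missingness patterns, forest of ORs, remission curves.

#' Stacked missingness-pattern bars per visit and cohort
#'
#' @param labels Label table from [classify_missingness()] or the
#'   generator.
#' @return A ggplot.
#' @export
plot_missing_patterns <- function(labels) {
  pat <- summarize_patterns(labels)$by_visit
  p <- ggplot2::ggplot(
    pat,
    ggplot2::aes(x = factor(.data$visit_month), y = .data$proportion,
                 fill = .data$label)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1) +
    ggplot2::labs(x = "Visit (months)", y = "Proportion of subjects",
                  fill = "Missingness") +
    ggplot2::theme_minimal()
  if ("cohort" %in% names(pat)) p <- p + ggplot2::facet_wrap(~cohort)
  p
}

#' Forest plot of odds ratios per approach and visit
#'
#' @param object An `eca_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eca_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$effects,
    ggplot2::aes(x = .data$or, y = .data$approach)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~visit_month, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Odds ratio of remission (trial vs observational)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Estimated remission proportions per arm, approach and visit
#'
#' @param comparison An `eca_comparison`.
#' @return A ggplot.
#' @export
plot_remission_proportions <- function(comparison) {
  ggplot2::ggplot(
    comparison$proportions,
    ggplot2::aes(x = .data$visit_month, y = .data$proportion,
                 colour = .data$approach)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Visit (months)", y = "Estimated remission proportion",
                  colour = "Approach") +
    ggplot2::theme_minimal()
}
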