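# ggplot2 views of simulation results.

#' Plot per-variable inclusion frequencies
#'
#' One panel per evidence rule and scenario, true predictors and noise
#' variables distinguished by colour — the per-variable analogue of the
#' study-level indicators, useful for seeing which predictors a procedure
#' systematically misses (weak conditional effects under univariable
#' selection, collinear ones under backward elimination).
#'
#' @param object,results A `sim_results` object from [run_study()].
#' @param scenarios Optional character vector restricting the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_inclusion <- function(results, scenarios = NULL) {
  stopifnot(inherits(results, "sim_results"))
  data <- results$inclusion
  if (!is.null(scenarios)) {
    data <- dplyr::filter(data, .data$scenario %in% scenarios)
  }
  data$variable <- factor(data$variable, levels = unique(data$variable))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$variable,
                                     y = .data$frequency,
                                     fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rule ~ scenario,
                        labeller = ggplot2::labeller(
                          rule = function(r) paste0("rule ", r))) +
    ggplot2::scale_fill_manual(values = c(`true predictor` = "#2c7fb8",
                                          `non-predictor` = "grey55")) +
    ggplot2::labs(x = NULL, y = "inclusion frequency", fill = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @rdname plot_inclusion
#' @export
autoplot.sim_results <- function(object, scenarios = NULL, ...) {
  plot_inclusion(object, scenarios = scenarios)
}

#' Plot scenario-level performance indicators
#'
#' @inheritParams plot_inclusion
#' @param metrics Which indicators to show.
#' @return A ggplot object.
#' @export
plot_performance <- function(results,
                             metrics = c("msf", "tpr", "dmsf", "fpr",
                                         "fnr", "mspe")) {
  stopifnot(inherits(results, "sim_results"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  data <- tidyr::pivot_longer(results$summary,
                              cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  data$metric <- factor(data$metric, levels = metrics)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$scenario,
                                     y = .data$value,
                                     colour = factor(.data$rule),
                                     group = factor(.data$rule))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "rule") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
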