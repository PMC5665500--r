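#' Plot a performance metric against sample size
#'
#' Line plot of bias, precision or coverage by method, faceted by cutoff
#' when several cutoffs are present — the standard way to compare the
#' estimators across the sample-size grid.
#'
#' @param metrics A table from [summarize_metrics()].
#' @param metric `"bias"`, `"precision"` or `"coverage"`.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics,
                         metric = c("bias", "precision", "coverage")) {
  metric <- match.arg(metric)
  ycol <- switch(metric, bias = "mean_bias_pp", precision = "precision_pp",
                 coverage = "coverage")
  ylab <- switch(metric,
                 bias = "Mean bias (percentage points)",
                 precision = "Mean 95% CI half-width (percentage points)",
                 coverage = "Coverage of nominal 95% CI")
  check_slice(metrics, c("method", "sample_size", ycol), "plot_metrics")
  p <- ggplot2::ggplot(metrics,
                       ggplot2::aes(x = .data$sample_size,
                                    y = .data[[ycol]],
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Sample size", y = ylab, colour = "Method") +
    ggplot2::theme_minimal()
  if (metric == "coverage") {
    p <- p + ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed")
  }
  if ("cutoff_mm" %in% names(metrics) &&
      length(unique(metrics$cutoff_mm)) > 1) {
    p <- p + ggplot2::facet_wrap(
      ~cutoff_mm,
      labeller = ggplot2::as_labeller(function(v)
        paste0("MUAC < ", v, " mm")))
  }
  p
}

#' Plot threshold classification performance
#'
#' Probability of correctly flagging prevalence at or above each threshold,
#' by method and sample size.
#'
#' @param class_table A table from [classification_table()].
#' @return A ggplot object.
#' @export
plot_classification <- function(class_table) {
  check_slice(class_table, c("method", "sample_size", "threshold",
                             "p_correct"), "plot_classification")
  ggplot2::ggplot(class_table,
                  ggplot2::aes(x = .data$sample_size,
                               y = .data$p_correct,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~threshold,
                        labeller = ggplot2::as_labeller(function(v)
                          paste0("Threshold ", v, "%"))) +
    ggplot2::labs(x = "Sample size",
                  y = "P(correctly classified above threshold)",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a bias regression
#'
#' @param object A `bias_regression`.
#' @param ... Unused.
#' @return A ggplot object (forest-style plot of coefficients and 95% CIs).
#' @export
autoplot.bias_regression <- function(object, ...) {
  td <- tidy(object)
  td <- td[!td$reference, , drop = FALSE]
  td$label <- paste(td$term, td$level, sep = ": ")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Coefficient (percentage points of bias)", y = NULL) +
    ggplot2::theme_minimal()
}
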