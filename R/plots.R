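#' Box plots of experiment log-likelihood distributions
#'
#' One plotting helper per experiment design, all returning ggplot objects in
#' the style conventional for these comparisons: per-center (or per-step, or
#' per-keep-fraction) box plots of the normalized predictive log-likelihood
#' distribution, colored by condition, with the pooled-data baseline as a
#' dashed reference line where available.
#'
#' @param result A result tibble from one of the `run_*` experiment drivers.
#' @param trim_quantile Lower quantile at which the y axis is clipped (local
#'   fits on degenerate data can produce extreme outliers that would
#'   otherwise dominate the scale); `0` disables clipping.
#' @return A ggplot object.
#' @export
plot_combined_vs_local <- function(result, trim_quantile = 0.02) {
  df <- result[result$condition != "pooled", ]
  pooled <- result$loglik[result$condition == "pooled"]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$center),
                                        y = .data$loglik,
                                        fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, position = "dodge") +
    ggplot2::labs(x = "center", y = "normalized predictive log-likelihood",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (length(pooled) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = stats::median(pooled),
                                 linetype = "dashed")
  }
  clip_y(p, df$loglik, trim_quantile)
}

#' @rdname plot_combined_vs_local
#' @export
plot_incremental <- function(result, trim_quantile = 0.02) {
  p <- ggplot2::ggplot(result, ggplot2::aes(x = factor(.data$step),
                                            y = .data$loglik)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "steelblue") +
    ggplot2::facet_wrap(~center, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "other parties' synthetic data sets added",
                  y = "normalized predictive log-likelihood") +
    ggplot2::theme_minimal()
  clip_y(p, result$loglik, trim_quantile)
}

#' @rdname plot_combined_vs_local
#' @export
plot_size_sweep <- function(result, trim_quantile = 0.02) {
  p <- ggplot2::ggplot(result, ggplot2::aes(x = factor(.data$fraction),
                                            y = .data$loglik,
                                            fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, position = "dodge") +
    ggplot2::labs(x = "fraction of local training data",
                  y = "normalized predictive log-likelihood", fill = NULL) +
    ggplot2::theme_minimal()
  clip_y(p, result$loglik, trim_quantile)
}

#' @rdname plot_combined_vs_local
#' @export
plot_skew <- function(result, trim_quantile = 0.02) {
  p <- ggplot2::ggplot(result, ggplot2::aes(x = factor(.data$keep_fraction),
                                            y = .data$loglik,
                                            fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, position = "dodge") +
    ggplot2::labs(x = "fraction of the depleted two-way cell kept",
                  y = "subgroup predictive log-likelihood", fill = NULL) +
    ggplot2::theme_minimal()
  clip_y(p, result$loglik, trim_quantile)
}

clip_y <- function(p, values, trim_quantile) {
  if (trim_quantile > 0 && length(values) > 0) {
    lims <- c(stats::quantile(values, trim_quantile, names = FALSE),
              max(values))
    p <- p + ggplot2::coord_cartesian(ylim = lims)
  }
  p
}

#' Autoplot method for experiment result tables
#'
#' Dispatches to the plot helper matching the result's experiment type.
#'
#' @param object A `dpcollab_result` tibble.
#' @param ... Passed to the underlying `plot_*` helper.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot dpcollab_result
#' @export
autoplot.dpcollab_result <- function(object, ...) {
  switch(attr(object, "experiment"),
         combined_vs_local = plot_combined_vs_local(object, ...),
         incremental = plot_incremental(object, ...),
         size_sweep = plot_size_sweep(object, ...),
         skew = plot_skew(object, ...),
         stop("unknown experiment type"))
}

#' @export
ggplot2::autoplot
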