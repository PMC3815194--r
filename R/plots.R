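#' Box plot of intron/exon ratio distributions per timepoint
#'
#' The classic view of a retention time course: one box per timepoint over
#' the replicate-averaged intron/exon ratios of all scored introns.
#'
#' @param retention A `retention_table` from [compute_ratios()].
#' @param log_scale Show ratios on a log10 axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_retention_distributions <- function(retention, log_scale = TRUE) {
  d <- retention$summary |>
    mutate(timepoint = factor(.data$timepoint,
                              levels = sort(unique(.data$timepoint))))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint,
                                       y = .data$mean_ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = "time (min)", y = "intron/exon ratio",
                  title = "Intron retention over the time course") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Fold-change exceedance per timepoint
#'
#' @param time_course Tibble from [retention_time_course()].
#' @return A ggplot object (bar chart of the fraction of introns above the
#'   fold-change threshold).
#' @export
plot_exceedance <- function(time_course) {
  ggplot2::ggplot(time_course,
                  ggplot2::aes(x = factor(.data$timepoint),
                               y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "time (min)", y = "introns above threshold",
                  title = "Retention fold-change exceedance") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression results
#'
#' @param de Tibble from [differential_expression()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' @rdname plot_standard_curve
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @export
autoplot.standard_curve <- function(object, ...) {
  plot_standard_curve(object)
}

#' Plot a qPCR standard curve
#'
#' Cq against log10 input with the fitted dilution line and the derived
#' amplification efficiency in the subtitle.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
plot_standard_curve <- function(curve) {
  ggplot2::ggplot(curve$points, ggplot2::aes(x = log10(.data$input_ng),
                                             y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = curve$slope, intercept = curve$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 input (ng)", y = "Cq",
      title = if (is.na(curve$target)) "Standard curve" else curve$target,
      subtitle = sprintf("slope %.3f, E = %.2f, r^2 = %.4f",
                         curve$slope, curve$efficiency, curve$r_squared)
    ) +
    ggplot2::theme_minimal()
}
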