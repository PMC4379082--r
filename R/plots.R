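#' Plot a growth chart
#'
#' Shows the P10-P90 band, the median, and the mean per completed week.
#'
#' @param object A `uh_growth_chart`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uh_growth_chart
#' @export
autoplot.uh_growth_chart <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$week)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p10_cm, ymax = .data$p90_cm),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50_cm), color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_cm), size = 1) +
    ggplot2::labs(
      title = sprintf("Uterine height growth chart (%s)", chart_site(object)),
      x = "completed weeks of gestation", y = "uterine height (cm)"
    )
}

#' Bland-Altman agreement plot
#'
#' Per-pair differences against per-pair means, with the bias and 95%
#' limits of agreement.
#'
#' @param object A `uh_bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uh_bland_altman
#' @export
autoplot.uh_bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = object$bias, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(title = "Inter-operator agreement",
                  x = "mean of the two readings (cm)",
                  y = "difference op1 - op2 (cm)")
}

#' Plot one ROC curve
#'
#' @param object A `uh_roc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot uh_roc
#' @export
autoplot.uh_roc <- function(object, ...) plot_roc_curves(list(object))

#' Plot ROC curves over tape operating points
#'
#' One panel per endpoint, one trace per site, with the chance diagonal.
#' These are verification aids over the three discrete operating points,
#' not smoothed curves.
#'
#' @param curves A list of `uh_roc` objects.
#' @return A ggplot object.
#' @examples
#' tabs <- lapply(c("10-90", "50-50", "90-10"), load_fixture, site = "India")
#' plot_roc_curves(list(roc_curve(tabs, "20.0-35.6")))
#' @export
plot_roc_curves <- function(curves) {
  if (length(curves) == 0L) abort("no ROC curves to plot.")
  purrr::walk(curves, ~ stopifnot(inherits(.x, "uh_roc")))
  pts <- purrr::map_dfr(curves, tidy)
  labels <- purrr::map_dfr(curves, glance) |>
    dplyr::mutate(label = sprintf("%s AUC %.2f", .data$site, .data$auc))
  pts <- dplyr::left_join(pts, labels[c("site", "endpoint", "label")],
                          by = c("site", "endpoint"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    color = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, !.data$tape %in% c("(0,0)", "(1,1)"))) +
    ggplot2::facet_wrap(~ .data$endpoint) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity", color = NULL,
                  title = "ROC over tape operating points")
}

#' Render ROC curves to an image file
#'
#' @param curves A list of `uh_roc` objects.
#' @param path Output file (any device [ggplot2::ggsave()] supports).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
render_roc_plot <- function(curves, path, width = 8, height = 4.5) {
  p <- plot_roc_curves(curves)
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}
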