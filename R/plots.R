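# Diagnostic plots. Every function returns a ggplot object.

#' Plot true versus estimated fractions of a panel validation
#'
#' @param object `panel_validation` object from [validate_panel_insilico()].
#' @param ... Unused.
#' @return ggplot: per-cell-type scatter of true against estimated mixture
#'   fractions with the identity line.
#' @method autoplot panel_validation
#' @export
autoplot.panel_validation <- function(object, ...) {
  mx <- attr(object, "mixtures")
  long <- map_dfr(colnames(mx$estimated), function(ct) {
    tibble(cell_type = ct, true = mx$true[, match(ct, colnames(mx$estimated))],
           estimated = mx$estimated[, ct])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::labs(x = "true fraction", y = "estimated fraction",
                  title = "In-silico mixture validation") +
    ggplot2::theme_minimal()
}

#' Plot the interaction p-value distribution of a scan
#'
#' @param object `imqtl_scan` object.
#' @param ... Unused.
#' @return ggplot histogram of the tested term's p-values; a flat histogram
#'   is expected under the null.
#' @method autoplot imqtl_scan
#' @export
autoplot.imqtl_scan <- function(object, ...) {
  term <- object$meta$term
  ggplot2::ggplot(object$associations,
                  ggplot2::aes(x = .data[[term]])) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = sprintf("%s p-value", object$meta$cell_type),
                  y = "pairs") +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-cell-type effect sharing
#'
#' @param sharing `imqtl_sharing` object from [effect_sharing_matrix()].
#' @return ggplot tile map in dendrogram order; rows are the reference cell
#'   type.
#' @export
plot_sharing <- function(sharing) {
  long <- tidy(sharing) |>
    mutate(reference = factor(.data$reference, levels = sharing$order),
           other = factor(.data$other, levels = sharing$order))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$other, y = .data$reference,
                                     fill = .data$sharing)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$sharing)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "other cell type", y = "reference cell type",
                  fill = "shared") +
    ggplot2::theme_minimal()
}

#' Power against composition variance
#'
#' @param power_curve Tibble from [run_power_curve()].
#' @return ggplot of detection power against the variance of the modeled
#'   cell type's proportion.
#' @export
plot_power_curve <- function(power_curve) {
  ggplot2::ggplot(power_curve, ggplot2::aes(x = .data$prop_variance,
                                            y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "variance of cell-type proportion",
                  y = "detection power") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
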