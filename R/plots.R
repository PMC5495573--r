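#' Heatmap of a correlation matrix
#'
#' @param object A `corr_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.corr_matrix <- function(object, ...) {
  df <- tidy(object)
  df$row <- factor(df$row, levels = rev(object$row_ids))
  df$col <- factor(df$col, levels = object$col_ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("%s correlations (df = %d)",
                                  object$scope, object$df)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Box plot of grouped area-pair correlations
#'
#' Mirrors the homotopic/adjacent/distal (or corresponding/non-corresponding)
#' group summaries.
#'
#' @param groups Tibble from [group_homotopic_pairs()] or the `groups`
#'   element of [quadrant_matrix()].
#' @param group_col Grouping column name.
#' @return A ggplot.
#' @export
plot_pair_groups <- function(groups, group_col = "group") {
  ggplot2::ggplot(groups, ggplot2::aes(.data[[group_col]], .data$r)) +
    ggplot2::geom_boxplot(outlier.shape = 4, fill = "grey85") +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 21,
                          fill = "white", size = 2.5) +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_classic()
}

#' MDS embedding colored by community
#'
#' @param object A `cluster_result` from [structure_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   color = factor(.data$community),
                                   label = .data$area)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -0.8, show.legend = FALSE) +
    ggplot2::labs(color = "community",
                  title = sprintf("Q = %.2f, stress = %.3f",
                                  object$communities$Q,
                                  object$embedding$stress)) +
    ggplot2::theme_minimal()
}

#' Eccentricity-band correlation curve with its Gaussian fit
#'
#' @param curve Per-band correlation vector.
#' @param fit An `ecc_fit` for the curve (refit if omitted).
#' @return A ggplot.
#' @export
plot_ecc_curve <- function(curve, fit = fit_gaussian_peak(curve)) {
  x <- seq_along(curve)
  xx <- seq(1, length(curve), by = 0.05)
  yy <- fit$A0 + fit$A1 * exp(-((xx - fit$B1) / fit$C1)^2)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = data.frame(x = x, y = curve),
                        ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line(data = data.frame(x = xx, y = yy),
                       ggplot2::aes(.data$x, .data$y), color = "#b2182b") +
    ggplot2::geom_vline(xintercept = fit$B1, linetype = 2) +
    ggplot2::labs(x = "V1 eccentricity band", y = "Pearson r",
                  title = sprintf("peak at band %.2f (passed: %s)",
                                  fit$B1, fit$passed)) +
    ggplot2::theme_classic()
}

#' Decoded phase map against the planted values
#'
#' @param pm A decoded `phase_map` (see [decode_phase()]).
#' @param planted Planted per-voxel values (same units).
#' @return A ggplot.
#' @export
plot_phase_recovery <- function(pm, planted) {
  df <- data.frame(planted = planted, decoded = pm$decoded_value)
  ggplot2::ggplot(df, ggplot2::aes(.data$planted, .data$decoded)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "#b2182b") +
    ggplot2::labs(x = "planted value", y = "decoded value") +
    ggplot2::theme_classic()
}
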