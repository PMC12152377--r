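#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted dose-response curve
#'
#' Draws the fitted three-parameter logistic curve on a log concentration
#' axis together with the viability points it was fit to.
#'
#' @param object A `curve_fit_3pl`.
#' @param n Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot curve_fit_3pl
#' @export
autoplot.curve_fit_3pl <- function(object, n = 200, ...) {
  xr <- range(object$concs)
  xs <- exp(seq(log(xr[1]), log(xr[2]), length.out = n))
  line <- tibble::tibble(conc = xs, viability = curve_eval(object, xs))
  pts <- tibble::tibble(conc = object$concs, viability = object$viabilities)
  ggplot2::ggplot(line, ggplot2::aes(x = .data$conc, y = .data$viability)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(data = pts) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "concentration (µM)", y = "relative viability",
                  title = sprintf("3PL fit (b=%.2f, c=%.2f, e=%.3g µM, RMSE %.3f)",
                                  object$b, object$c, object$e, object$rmse)) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response matrix as a viability heatmap
#'
#' @param object A `dose_response_matrix`.
#' @param ... Unused.
#' @return A ggplot; missing cells are blank.
#' @method autoplot dose_response_matrix
#' @export
autoplot.dose_response_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_along(object$row_concs),
                           j = seq_along(object$col_concs))
  df$viability <- object$viability[cbind(df$i, df$j)]
  df$conc_a <- factor(conc_key(object$row_concs)[df$i],
                      levels = conc_key(object$row_concs))
  df$conc_b <- factor(conc_key(object$col_concs)[df$j],
                      levels = conc_key(object$col_concs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc_b, y = .data$conc_a,
                                   fill = .data$viability)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::labs(x = paste0(object$drug_col, " (µM)"),
                  y = paste0(object$drug_row, " (µM)"),
                  title = paste("Dose-response matrix,", object$cell_line)) +
    ggplot2::theme_minimal()
}

#' Plot grouped error metrics
#'
#' One point per group for the chosen metric, a quick diagnostic for
#' per-drug/per-combination/per-interval performance.
#'
#' @param object An `error_summary`.
#' @param metric `"mae"`, `"pcc"` or `"r2"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot error_summary
#' @export
autoplot.error_summary <- function(object, metric = c("mae", "pcc", "r2"), ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "grouping"), y = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Compare actual and predicted treatment rankings graphically
#'
#' Scatter of actual versus predicted rank, one point per treatment; the
#' diagonal marks perfect agreement.
#'
#' @param actual,predicted `treatment_ranking` objects over the same
#'   treatments.
#' @return A ggplot.
#' @export
plot_ranking_comparison <- function(actual, predicted) {
  m <- match(actual$treatment, predicted$treatment)
  df <- tibble::tibble(treatment = actual$treatment, type = actual$type,
                       actual_rank = actual$rank, predicted_rank = predicted$rank[m])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual_rank, y = .data$predicted_rank,
                                   color = .data$type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "actual rank", y = "predicted rank") +
    ggplot2::theme_minimal()
}
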