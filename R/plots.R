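#' Plot a population trend fit over its subject-exam scatter
#'
#' @param object A `trend_fit`.
#' @param data Optional subject-summary tibble to draw as scatter behind the
#'   fitted curve (thinned to at most `max_points` points).
#' @param max_points Scatter thinning cap.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, data = NULL, max_points = 2000, ...) {
  grid <- tibble::tibble(age = seq(object$ref_age, 90, by = 0.5))
  grid$y <- predict(object, grid$age)
  ylab <- if (object$response == "excess_bmi") "excess BMI (kg/m²)" else "height loss (cm)"
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$age, y = .data$y))
  if (!is.null(data)) {
    pts <- data[data$age >= object$ref_age & !is.na(data[[object$response]]), ]
    if (nrow(pts) > max_points) pts <- pts[seq(1, nrow(pts), length.out = max_points), ]
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$age, y = .data[[object$response]]),
      alpha = 0.15, size = 0.4, colour = "grey40", inherit.aes = FALSE)
  }
  p + ggplot2::geom_line(linewidth = 1, colour = "#b2182b") +
    ggplot2::labs(x = "age (years)", y = ylab) +
    ggplot2::theme_minimal()
}

#' 2x2 panel plot of the misclassification curves
#'
#' Fraction misclassified versus age, faceted by category (overweight/obese)
#' and denominator (population/category), one line per sex.
#'
#' @param curve Output of [misclassification_curve()].
#' @return A ggplot.
#' @export
plot_misclassification <- function(curve) {
  curve |>
    dplyr::filter(!is.na(.data$fraction)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$age_bin, y = .data$fraction,
                                 colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(category ~ denominator) +
    ggplot2::labs(x = "age (years)", y = "fraction misclassified",
                  colour = "sex") +
    ggplot2::theme_minimal()
}

#' Relative-risk curves: current (solid) vs corrected (dashed) BMI
#'
#' @param rr Output of [rr_curves()] or [rr_by_age()].
#' @param diseases Diseases to include.
#' @return A ggplot faceted by disease and sex.
#' @export
plot_relative_risk <- function(rr, diseases = unique(rr$disease)) {
  rr |>
    dplyr::filter(.data$disease %in% diseases, !is.na(.data$rr)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$age_bin, y = .data$rr,
                                 linetype = .data$bmi_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60", linewidth = 0.3) +
    ggplot2::facet_grid(disease ~ sex, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(current = "solid", corrected = "dashed")) +
    ggplot2::labs(x = "age (years)", y = "relative risk (obese vs non-obese)",
                  linetype = "BMI") +
    ggplot2::theme_minimal()
}

pipeline_figures <- function(result) {
  figs <- list()
  lin <- grep("^shrinkage_linear_", names(result$trends), value = TRUE)
  if (length(lin) > 0) {
    figs$fig1_height_loss <- autoplot(result$trends[[lin[1]]], result$summaries)
  }
  exc <- grep("^excess_bmi_", names(result$trends), value = TRUE)
  if (length(exc) > 0) {
    figs$fig2_excess_bmi <- autoplot(result$trends[[exc[1]]], result$summaries)
  }
  figs$fig3_misclassification <- plot_misclassification(result$misclassification)
  figs$fig4_glycemic_rr <- plot_relative_risk(
    result$relative_risk, c("prediabetes", "diabetes"))
  figs$fig5_hypertension_rr <- plot_relative_risk(
    result$relative_risk, "hypertension")
  figs
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
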