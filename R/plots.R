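# ggplot2 visualizations for the main result types.

#' @describeIn fit_linear Plot the series and fitted line.
#' @param object A `linear_fit`.
#' @export
autoplot.linear_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point() +
    {
      if ("se" %in% names(d)) {
        ggplot2::geom_errorbar(
          ggplot2::aes(ymin = .data$response - .data$se,
                       ymax = .data$response + .data$se),
          width = 0.2
        )
      }
    } +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "Dose (Gy)", y = "Response",
                  title = sprintf("Linear dose response: slope %.3g / Gy",
                                  object$slope))
}

#' @describeIn fit_plateau Plot the series and fitted saturation curve.
#' @param object A `plateau_fit`.
#' @export
autoplot.plateau_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(dose = seq(0, max(d$dose), length.out = 200))
  grid$response <- object$plateau -
    (object$plateau - 1) * exp(-object$rate * grid$dose)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Dose (Gy)", y = "Fold change",
                  title = sprintf("Plateau fit: P = %.3g, k = %.3g / Gy",
                                  object$plateau, object$rate))
}

#' @describeIn fit_lq Plot surviving fractions and the fitted LQ curve on a
#'   log scale.
#' @param object An `lq_fit`.
#' @export
autoplot.lq_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(dose = seq(0, max(d$dose), length.out = 200))
  grid$sf <- exp(-object$alpha * grid$dose - object$beta * grid$dose^2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dose, y = .data$sf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction",
                  title = sprintf("LQ fit: alpha = %.3g /Gy, beta = %.3g /Gy^2",
                                  object$alpha, object$beta))
}

#' Heat map of a Z-score matrix
#'
#' @param zscores Result of [zscore_matrix()] (or a plain matrix).
#' @return A ggplot object (genes as rows, conditions as columns, diverging
#'   fill as in the usual expression heat maps).
#' @export
plot_zscore_heatmap <- function(zscores) {
  z <- if (is.list(zscores)) zscores$z else zscores
  d <- tibble::as_tibble(z, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "condition", values_to = "z")
  d$gene <- factor(d$gene, levels = rev(rownames(z)))
  d$condition <- factor(d$condition, levels = colnames(z))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$gene,
                                  fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "black",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z")
}

#' Per-group focus counts with background-corrected means
#'
#' @param corrected Output of [background_correct()].
#' @return A ggplot object of corrected mean foci/cell vs dose by quality.
#' @export
plot_foci_dose_response <- function(corrected) {
  ggplot2::ggplot(corrected,
                  ggplot2::aes(x = .data$dose, y = .data$corrected_mean,
                               colour = .data$quality)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$corrected_mean - .data$se_foci,
                   ymax = .data$corrected_mean + .data$se_foci),
      width = 0.2
    ) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Dose (Gy)",
                  y = "Cytoplasmic dsDNA foci per cell (background-corrected)")
}
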