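# broom-style tidy()/glance() methods for the fitted objects.

#' @describeIn fit_linear Tidy the coefficients of a linear dose-response fit.
#' @param x A `linear_fit` object.
#' @param ... Unused.
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = c(x$se_intercept, x$se_slope)
  ) |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * pt(-abs(.data$statistic), x$df)
    )
}

#' @describeIn fit_linear One-row fit summary.
#' @export
glance.linear_fit <- function(x, ...) {
  tibble::tibble(df_residual = x$df, sigma2 = x$sigma2,
                 n = nrow(x$data))
}

#' @describeIn fit_plateau Tidy the plateau-fit coefficients.
#' @param x A `plateau_fit` object.
#' @param ... Unused.
#' @export
tidy.plateau_fit <- function(x, ...) {
  tibble::tibble(
    term = c("plateau", "rate"),
    estimate = c(x$plateau, x$rate),
    std_error = c(x$se_plateau, x$se_rate)
  )
}

#' @describeIn fit_plateau One-row fit summary.
#' @export
glance.plateau_fit <- function(x, ...) {
  tibble::tibble(df_residual = x$df, rss = x$rss,
                 degenerate = isTRUE(x$degenerate), n = nrow(x$data))
}

#' @describeIn fit_lq Tidy the LQ coefficients.
#' @param x An `lq_fit` object.
#' @param ... Unused.
#' @export
tidy.lq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std_error = unname(x$se)
  )
}

#' @describeIn fit_lq One-row fit summary.
#' @export
glance.lq_fit <- function(x, ...) {
  tibble::tibble(df_residual = x$df, rss = x$rss,
                 boundary = isTRUE(x$boundary), n = nrow(x$data))
}
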