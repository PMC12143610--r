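# Dose-response fitting and comparison across radiation qualities.
#
# Fit observations are per-dose group means (matching the mean +/- SD
# presentation of focus counts and fold changes), weighted by 1/SE^2 when
# standard errors are available.

check_series <- function(series, need_zero = FALSE) {
  stopifnot(all(c("dose", "response") %in% names(series)))
  if (any(series$dose < 0)) abort("doses must be >= 0")
  if (dplyr::n_distinct(series$dose) < 3) {
    abort("at least 3 distinct doses are required")
  }
  if (need_zero && !any(series$dose == 0)) {
    abort("series must include a 0 Gy point")
  }
  invisible(series)
}

series_weights <- function(series) {
  if ("se" %in% names(series) && all(is.finite(series$se)) &&
      all(series$se > 0)) {
    1 / series$se^2
  } else {
    rep(1, nrow(series))
  }
}

#' Fit a straight line to a dose-response series
#'
#' Weighted least squares of `response ~ dose` (weights `1/se^2` when an `se`
#' column with positive finite values is present, unweighted otherwise),
#' with a free intercept by default. Background-subtracted focus counts pass
#' near the origin anyway; a through-origin fit is available via
#' `intercept = FALSE`.
#'
#' @param series Tibble with columns `dose`, `response` and optionally `se`,
#'   `n`, `quality`, `endpoint`.
#' @param intercept Fit a free intercept (default TRUE).
#' @return An object of class `linear_fit` with `slope`, `intercept`, their
#'   standard errors, `df`, the covariance matrix and the data.
#' @export
fit_linear <- function(series, intercept = TRUE) {
  series <- tibble::as_tibble(series)
  check_series(series)
  if (dplyr::n_distinct(series$dose) == 1L || sd(series$dose) == 0) {
    abort("zero dose variance: cannot fit a slope")
  }
  w <- series_weights(series)
  X <- if (intercept) cbind(1, series$dose) else cbind(series$dose)
  y <- series$response
  XtW <- t(X * w)
  xtx <- XtW %*% X
  beta <- solve(xtx, XtW %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  if (df < 1) abort("at least one residual degree of freedom is required")
  s2 <- sum(w * res^2) / df
  covb <- s2 * solve(xtx)
  slope_i <- if (intercept) 2L else 1L
  structure(
    list(
      slope = beta[slope_i],
      intercept = if (intercept) beta[1] else 0,
      se_slope = sqrt(covb[slope_i, slope_i]),
      se_intercept = if (intercept) sqrt(covb[1, 1]) else 0,
      df = df,
      sigma2 = s2,
      cov = covb,
      residuals = as.numeric(res),
      data = series,
      quality = if ("quality" %in% names(series)) series$quality[1] else NA_character_
    ),
    class = "linear_fit"
  )
}

#' Compare the slopes of two linear dose-response fits
#'
#' Two-sample t-test on the fitted slopes:
#' `t = (slope_A - slope_B) / sqrt(se_A^2 + se_B^2)`, with Welch-Satterthwaite
#' degrees of freedom computed from the two slope variances and the fits'
#' residual degrees of freedom; the p-value is two-sided.
#'
#' @param fit_a,fit_b `linear_fit` objects.
#' @return A tibble with `estimate` (slope difference), `t`, `df`, `p_value`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "linear_fit"), inherits(fit_b, "linear_fit"),
            fit_a$df >= 1, fit_b$df >= 1)
  v_a <- fit_a$se_slope^2
  v_b <- fit_b$se_slope^2
  if (v_a + v_b <= 0) abort("zero combined standard error: slopes are exact")
  t_stat <- (fit_a$slope - fit_b$slope) / sqrt(v_a + v_b)
  df <- (v_a + v_b)^2 / (v_a^2 / fit_a$df + v_b^2 / fit_b$df)
  tibble::tibble(
    estimate = fit_a$slope - fit_b$slope,
    t = t_stat, df = df,
    p_value = 2 * pt(-abs(t_stat), df)
  )
}

#' Fit an exponential-saturation (plateau) dose response
#'
#' Fits `y(D) = P - (P - 1) * exp(-k * D)` by nonlinear least squares, with
#' the baseline fixed at `y(0) = 1`: the response is a fold change relative
#' to the unirradiated control, which is definitionally 1. `P` is the
#' plateau fold change reached at high dose and `k` (1/Gy) the approach
#' rate. Starting values are `P = max(response)` and `k = 1/max(dose)`;
#' on non-convergence up to `restarts` jittered restarts are attempted.
#'
#' A flat series at 1 leaves `k` unidentifiable; the fit is returned with
#' `P = 1`, `k = 0` and `degenerate = TRUE` rather than erroring.
#'
#' @param series Tibble with `dose`, `response` (fold change) and optional
#'   `se` column; must include a 0 Gy point.
#' @param restarts Maximum number of jittered restarts (default 8).
#' @return An object of class `plateau_fit` with `plateau`, `rate`, standard
#'   errors, `df`, residuals and the data.
#' @export
fit_plateau <- function(series, restarts = 8) {
  series <- tibble::as_tibble(series)
  check_series(series, need_zero = TRUE)
  w <- series_weights(series)
  if (sd(series$response) < 1e-12) {
    return(structure(
      list(plateau = 1, rate = 0, se_plateau = NA_real_, se_rate = NA_real_,
           df = nrow(series) - 2L, rss = sum(w * (series$response - 1)^2),
           residuals = series$response - 1, data = series,
           degenerate = TRUE),
      class = "plateau_fit"
    ))
  }
  dat <- data.frame(D = series$dose, y = series$response, w = w)
  start <- list(P = max(max(series$response), 1.05),
                k = 1 / max(max(series$dose), 1))
  fit <- NULL
  for (r in seq_len(restarts + 1L)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ P - (P - 1) * exp(-k * D),
        data = dat, start = start, weights = dat$w,
        lower = c(P = -Inf, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (!inherits(fit, "error")) break
    start <- list(P = start$P * exp(runif(1, -0.5, 0.5)),
                  k = start$k * exp(runif(1, -1, 1)))
  }
  if (inherits(fit, "error")) {
    abort(paste("plateau fit did not converge after", restarts,
                "restarts:", conditionMessage(fit)))
  }
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(
    list(plateau = unname(est["P"]), rate = unname(est["k"]),
         se_plateau = unname(se["P"]), se_rate = unname(se["k"]),
         df = nrow(series) - 2L,
         rss = sum(w * residuals(fit)^2),
         residuals = as.numeric(residuals(fit)),
         data = series, degenerate = FALSE),
    class = "plateau_fit"
  )
}

#' Compare two dose-response fits by an extra-sum-of-squares F-test
#'
#' Tests whether two groups share one dose-response curve: the pooled model
#' fits a single parameter set to both series, the separate model fits each
#' series on its own, and the nested models are compared with
#' `F = ((RSS_pooled - RSS_sep) / (df_pooled - df_sep)) / (RSS_sep / df_sep)`.
#' Works for `plateau_fit` (and `linear_fit`) pairs; both fits must be of
#' the same model class.
#'
#' @param fit_a,fit_b Two fits of the same class (`plateau_fit` or
#'   `linear_fit`), each still carrying its data.
#' @return A tibble with `F`, `df1`, `df2`, `p_value`, `rss_pooled`,
#'   `rss_separate`.
#' @export
compare_fits <- function(fit_a, fit_b) {
  if (!identical(class(fit_a), class(fit_b))) {
    abort("fits are not nested: both must be of the same model class")
  }
  pooled_data <- dplyr::bind_rows(fit_a$data, fit_b$data)
  if (inherits(fit_a, "plateau_fit")) {
    pooled <- fit_plateau(pooled_data)
    rss_sep <- fit_a$rss + fit_b$rss
    rss_pool <- pooled$rss
    p_sep <- 4L
    p_pool <- 2L
  } else if (inherits(fit_a, "linear_fit")) {
    pooled <- fit_linear(pooled_data)
    w_a <- series_weights(fit_a$data)
    w_b <- series_weights(fit_b$data)
    rss_sep <- sum(w_a * fit_a$residuals^2) + sum(w_b * fit_b$residuals^2)
    rss_pool <- sum(series_weights(pooled_data) * pooled$residuals^2)
    p_sep <- 4L
    p_pool <- 2L
  } else {
    abort("unsupported fit class")
  }
  n <- nrow(pooled_data)
  df2 <- n - p_sep
  df1 <- p_sep - p_pool
  if (df2 < 1) abort("not enough points for the separate-fits model")
  f_stat <- max(((rss_pool - rss_sep) / df1) / (rss_sep / df2), 0)
  tibble::tibble(
    F = f_stat, df1 = df1, df2 = df2,
    p_value = pf(f_stat, df1, df2, lower.tail = FALSE),
    rss_pooled = rss_pool, rss_separate = rss_sep
  )
}

#' Compare groups with the study's standard tests
#'
#' Two numeric vectors are compared with an unpaired two-tailed Welch
#' t-test. A data frame with a response and two factors is analyzed with a
#' two-way ANOVA (with interaction) followed by Tukey's multiple-comparisons
#' test on adjusted p-values.
#'
#' @param x Numeric vector (group A) or a data frame for the factorial
#'   layout.
#' @param y Numeric vector (group B); ignored for the factorial layout.
#' @param response,factor_a,factor_b Column names for the factorial layout.
#' @return For two groups: a tibble `estimate, t, df, p_value`. For the
#'   factorial layout: a list with `anova` (tidy two-way ANOVA table) and
#'   `tukey` (tibble of pairwise contrasts with adjusted p-values).
#' @export
compare_groups <- function(x, y = NULL, response = NULL, factor_a = NULL,
                           factor_b = NULL) {
  if (is.data.frame(x)) {
    stopifnot(!is.null(response), !is.null(factor_a), !is.null(factor_b))
    d <- data.frame(
      y = x[[response]],
      fa = factor(x[[factor_a]]),
      fb = factor(x[[factor_b]])
    )
    fit <- aov(y ~ fa * fb, data = d)
    an <- summary(fit)[[1]]
    anova_tbl <- tibble::tibble(
      term = trimws(rownames(an)),
      df = an$Df, sumsq = an$`Sum Sq`, statistic = an$`F value`,
      p_value = an$`Pr(>F)`
    )
    tk <- TukeyHSD(fit)
    tukey_tbl <- purrr::imap(tk, function(m, term) {
      tibble::tibble(
        term = term, contrast = rownames(m),
        estimate = m[, "diff"], conf_low = m[, "lwr"],
        conf_high = m[, "upr"], adj_p_value = m[, "p adj"]
      )
    }) |> dplyr::bind_rows()
    return(list(anova = anova_tbl, tukey = tukey_tbl))
  }
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2 || length(y) < 2) {
    abort("at least 2 observations per group are required")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate: both groups constant; identical -> no evidence of
    # difference (p = 1), different -> certain difference (p = 0)
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(estimate = mean(x) - mean(y), t = NA_real_,
                          df = NA_real_, p_value = if (same) 1 else 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    estimate = unname(ht$estimate[1] - ht$estimate[2]),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit> slope", signif(x$slope, 4), "+/-", signif(x$se_slope, 3),
      "per Gy; intercept", signif(x$intercept, 4), "; df", x$df, "\n")
  invisible(x)
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat("<plateau_fit> plateau", signif(x$plateau, 4), "; rate",
      signif(x$rate, 4), "/Gy; df", x$df,
      if (isTRUE(x$degenerate)) "(degenerate: flat series)" else "", "\n")
  invisible(x)
}
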