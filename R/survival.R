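# Clonogenic survival: plating efficiency, surviving fractions, the
# linear-quadratic model and RBE at a chosen iso-survival level.

#' Surviving fractions from colony counts
#'
#' Plating efficiency (PE) is the mean colonies/seeded ratio of the 0 Gy
#' flasks, computed per radiation quality; each flask's surviving fraction is
#' `SF = (colonies/seeded) / PE`, summarized per dose as mean +/- SE.
#'
#' Two standard errors are reported per dose group: `se`, the between-flask
#' empirical SE of the replicate SFs, and `se_count`, the binomial counting
#' error of the pooled colony count (`sqrt(p(1-p)/n)/PE` with `p` the pooled
#' colonies/seeded fraction). With typical triplicate designs the empirical
#' SE has only 2 degrees of freedom, so downstream fitting weights use the
#' counting error.
#'
#' @param data Tibble with columns `dose`, `quality`, `replicate`,
#'   `cells_seeded`, `colonies_counted` (one row per flask), e.g. from
#'   [simulate_survival_data()].
#' @return A list with `replicates` (per-flask SF) and `summary` (per
#'   (quality, dose): `sf`, `se`, `se_count`, `n`, `plating_efficiency`).
#' @export
surviving_fractions <- function(data) {
  stopifnot(all(c("dose", "quality", "cells_seeded", "colonies_counted")
                %in% names(data)))
  if (any(data$colonies_counted > data$cells_seeded)) {
    abort("colonies_counted cannot exceed cells_seeded")
  }
  pe <- data |>
    dplyr::filter(.data$dose == 0) |>
    dplyr::group_by(.data$quality) |>
    dplyr::summarise(
      plating_efficiency = mean(.data$colonies_counted / .data$cells_seeded),
      .groups = "drop"
    )
  missing <- setdiff(unique(data$quality), pe$quality)
  if (length(missing)) {
    abort(paste("no 0 Gy rows for quality:", paste(missing, collapse = ", ")))
  }
  if (any(pe$plating_efficiency == 0)) {
    abort("plating efficiency is 0: no colonies in the 0 Gy flasks")
  }
  reps <- data |>
    dplyr::left_join(pe, by = "quality") |>
    dplyr::mutate(
      sf = (.data$colonies_counted / .data$cells_seeded) /
        .data$plating_efficiency
    )
  summary <- reps |>
    dplyr::group_by(.data$quality, .data$dose) |>
    dplyr::summarise(
      n = dplyr::n(),
      se = sd(.data$sf) / sqrt(dplyr::n()),
      sf = mean(.data$sf),
      pooled_p = sum(.data$colonies_counted) / sum(.data$cells_seeded),
      n_seeded = sum(.data$cells_seeded),
      plating_efficiency = .data$plating_efficiency[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se_count = sqrt(.data$pooled_p * (1 - .data$pooled_p) / .data$n_seeded) /
        .data$plating_efficiency
    ) |>
    dplyr::select("quality", "dose", "sf", "se", "se_count", "n",
                  "plating_efficiency") |>
    dplyr::arrange(.data$quality, .data$dose)
  list(replicates = reps, summary = summary)
}

#' Fit the linear-quadratic survival model
#'
#' Least squares of `ln SF = -(alpha * D + beta * D^2)` with both
#' coefficients constrained non-negative (fitting in log space with the
#' non-negativity constraint is common radiobiology practice). When the
#' summary carries standard errors, weights `1/SE(ln SF)^2` are used with
#' `SE(ln SF) = SE(SF)/SF`; a counting-error column `se_count` (see
#' [surviving_fractions()]) is preferred over the empirical `se`, because
#' variances estimated from triplicate flasks make unstable weights. Rows
#' with `SF <= 0` (e.g. zero-colony flasks at high dose) cannot enter the
#' log fit; they are dropped with a warning.
#'
#' The two-parameter non-negative least-squares problem is solved exactly by
#' an active-set enumeration: the unconstrained weighted fit is used if
#' feasible, otherwise the best of the single-parameter boundary fits.
#'
#' @param sf Tibble with columns `dose`, `sf` and optionally `se` (one row
#'   per dose; the 0 Gy row carries no information and is ignored).
#' @return An object of class `lq_fit` with `alpha` (1/Gy), `beta` (1/Gy^2),
#'   standard errors, covariance, `df` and the data used.
#' @export
fit_lq <- function(sf) {
  sf <- tibble::as_tibble(sf)
  stopifnot(all(c("dose", "sf") %in% names(sf)))
  d <- dplyr::filter(sf, .data$dose > 0)
  bad <- d$sf <= 0
  if (any(bad)) {
    warn(paste(sum(bad), "row(s) with SF <= 0 excluded from the log-space fit"))
    d <- d[!bad, , drop = FALSE]
  }
  if (dplyr::n_distinct(d$dose) < 3) {
    abort("at least 3 distinct positive doses with SF > 0 are required")
  }
  y <- -log(d$sf)                       # y = alpha*D + beta*D^2, y >= 0 model
  se_col <- if ("se_count" %in% names(d)) d$se_count
            else if ("se" %in% names(d)) d$se
            else NULL
  w <- if (!is.null(se_col) && all(is.finite(se_col)) && all(se_col > 0)) {
    (d$sf / se_col)^2                   # 1/SE(ln SF)^2
  } else {
    rep(1, nrow(d))
  }
  X <- cbind(D = d$dose, D2 = d$dose^2)

  wls <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    XtW <- t(Xs * w)
    xtx <- XtW %*% Xs
    beta <- solve(xtx, XtW %*% y)
    res <- y - Xs %*% beta
    rss <- sum(w * res^2)
    list(cols = cols, beta = as.numeric(beta), rss = rss, xtx = xtx,
         res = as.numeric(res))
  }
  full <- wls(c(1L, 2L))
  sol <- if (all(full$beta >= 0)) {
    full
  } else {
    cands <- list(wls(1L), wls(2L))
    cands <- purrr::keep(cands, ~ all(.x$beta >= 0))
    cands <- c(cands, list(list(cols = integer(), beta = numeric(),
                                rss = sum(w * y^2), xtx = NULL, res = y)))
    cands[[which.min(purrr::map_dbl(cands, "rss"))]]
  }
  alpha <- beta_q <- 0
  if (1L %in% sol$cols) alpha <- sol$beta[match(1L, sol$cols)]
  if (2L %in% sol$cols) beta_q <- sol$beta[match(2L, sol$cols)]
  df <- nrow(d) - length(sol$cols)
  s2 <- if (df > 0) sol$rss / df else NA_real_
  covb <- matrix(NA_real_, 2, 2, dimnames = list(c("alpha", "beta"),
                                                 c("alpha", "beta")))
  se <- c(alpha = NA_real_, beta = NA_real_)
  if (!is.null(sol$xtx) && df > 0) {
    cv <- s2 * solve(sol$xtx)
    nm <- c("alpha", "beta")[sol$cols]
    covb[nm, nm] <- cv
    se[nm] <- sqrt(diag(cv))
  }
  structure(
    list(alpha = alpha, beta = beta_q, se = se, cov = covb, df = df,
         rss = sol$rss, boundary = !all(full$beta >= 0), data = d),
    class = "lq_fit"
  )
}

#' Dose producing a given surviving fraction under an LQ fit
#'
#' Solves `beta * D^2 + alpha * D + ln(level) = 0` for the positive root;
#' when `beta = 0` the linear closed form `D = -ln(level)/alpha` is used.
#'
#' @param fit An `lq_fit` object.
#' @param level Target surviving fraction in (0, 1]; the conventional
#'   iso-survival level for RBE is 0.10.
#' @return Dose in Gy.
#' @export
dose_at_survival <- function(fit, level) {
  stopifnot(inherits(fit, "lq_fit"), level > 0, level <= 1)
  if (level == 1) return(0)
  if (fit$alpha + fit$beta <= 0) {
    abort("alpha + beta must be positive to reach the survival level")
  }
  l <- log(level)
  if (fit$beta == 0) {
    return(-l / fit$alpha)
  }
  disc <- fit$alpha^2 - 4 * fit$beta * l
  if (disc < 0) abort("no positive root at this survival level")
  (-fit$alpha + sqrt(disc)) / (2 * fit$beta)
}

#' Relative biological effectiveness at an iso-survival level
#'
#' `RBE = D_reference(level) / D_test(level)`: the ratio of reference-quality
#' dose (conventionally X-ray) to test-quality dose (e.g. carbon ions)
#' producing the same surviving fraction.
#'
#' @param fit_reference `lq_fit` of the reference radiation.
#' @param fit_test `lq_fit` of the test radiation.
#' @param level Surviving fraction at which to compare (default 0.10).
#' @return The RBE ratio (dimensionless).
#' @export
rbe <- function(fit_reference, fit_test, level = 0.10) {
  dose_at_survival(fit_reference, level) / dose_at_survival(fit_test, level)
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("<lq_fit> alpha", signif(x$alpha, 4), "/Gy; beta", signif(x$beta, 4),
      "/Gy^2; df", x$df,
      if (isTRUE(x$boundary)) "(non-negativity boundary active)" else "", "\n")
  invisible(x)
}
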