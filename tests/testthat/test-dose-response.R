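test_that("linear fit recovers exact lines and validates input", {
  d <- tibble::tibble(dose = c(0, 2, 4, 8), response = 0.5 * c(0, 2, 4, 8))
  fit <- fit_linear(d)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 4), tolerance = 1e-12)

  flat <- tibble::tibble(dose = c(0, 2, 4, 8), response = rep(3, 4))
  expect_equal(fit_linear(flat)$slope, 0, tolerance = 1e-12)

  expect_error(fit_linear(tibble::tibble(dose = c(0, 2), response = 1:2)),
               "3 distinct doses")
  expect_error(
    fit_linear(tibble::tibble(dose = c(2, 2, 2, 2), response = 1:4)),
    "3 distinct doses"
  )
})

test_that("dose rescaling rescales the slope exactly", {
  set.seed(11)
  d <- tibble::tibble(dose = c(0, 1, 2, 4, 8),
                      response = 1 + 0.3 * c(0, 1, 2, 4, 8) + rnorm(5, 0, 0.1))
  f1 <- fit_linear(d)
  f2 <- fit_linear(dplyr::mutate(d, dose = dose * 4))
  expect_equal(f2$slope, f1$slope / 4, tolerance = 1e-12)
})

test_that("slope comparison is antisymmetric and null on identical fits", {
  set.seed(2)
  mk <- function() {
    simulate_count_series(1, 0.2, c(0, 2, 4, 8, 12, 16), 50) |> fit_linear()
  }
  fa <- mk(); fb <- mk()
  same <- compare_slopes(fa, fa)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  ab <- compare_slopes(fa, fb)
  ba <- compare_slopes(fb, fa)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("slope recovery is within 3 SE of the generating slope", {
  set.seed(5)
  doses <- c(0, 2, 4, 8, 12, 16)
  for (s in c(0.1, 0.3)) {
    fit <- fit_linear(simulate_count_series(1, s, doses, 200))
    expect_lt(abs(fit$slope - s), 3 * fit$se_slope)
  }
})

test_that("plateau fit round-trips exact parameters and flags flat series", {
  d <- c(0, 2, 4, 8, 12, 20)
  y <- 4 - (4 - 1) * exp(-0.2 * d)
  fit <- fit_plateau(tibble::tibble(dose = d, response = y))
  expect_lt(abs(fit$plateau - 4) / 4, 1e-4)
  expect_lt(abs(fit$rate - 0.2) / 0.2, 1e-4)
  # the model form fixes y(0) = 1 for any parameters
  expect_equal(fit$plateau - (fit$plateau - 1) * exp(-fit$rate * 0), 1)

  flat <- fit_plateau(tibble::tibble(dose = d, response = rep(1, 6)))
  expect_true(flat$degenerate)
  expect_equal(flat$plateau, 1)

  # noisy recovery within 3 SE of the plateau
  set.seed(3)
  yn <- y * (1 + rnorm(6, 0, 0.1))
  fitn <- fit_plateau(tibble::tibble(dose = d, response = yn))
  expect_lt(abs(fitn$plateau - 4), 3 * fitn$se_plateau)
})

test_that("extra-sum-of-squares F-test sees identical and different trends", {
  d <- c(0, 2, 4, 8, 12, 20)
  set.seed(7)
  mk <- function(P) {
    y <- P - (P - 1) * exp(-0.25 * d) + rnorm(6, 0, 0.1)
    fit_plateau(tibble::tibble(dose = d, response = y))
  }
  a <- mk(4)
  same <- compare_fits(a, a)
  expect_lt(same$F, 1e-8)
  expect_gt(same$p_value, 0.999)

  b <- mk(12)
  diffr <- compare_fits(a, b)
  expect_lt(diffr$p_value, 0.05)

  lin <- fit_linear(tibble::tibble(dose = d, response = d))
  expect_error(compare_fits(a, lin), "same model class")
})

test_that("group comparison matches a hand-coded Welch t-test", {
  x <- c(4.1, 5.2, 6.0)
  y <- c(7.3, 8.1, 9.4)
  res <- compare_groups(x, y)
  # independent brute-force Welch computation
  vx <- var(x) / 3; vy <- var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  ident <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(ident$p_value, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("factorial layouts get a two-way ANOVA with Tukey adjustment", {
  set.seed(9)
  d <- tidyr::expand_grid(quality = c("x", "c"), dose = c(0, 8, 20),
                          rep = 1:4) |>
    dplyr::mutate(y = 2 * (quality == "c") + 0.3 * dose + rnorm(dplyr::n()))
  res <- compare_groups(d, response = "y", factor_a = "quality",
                        factor_b = "dose")
  expect_true(all(c("anova", "tukey") %in% names(res)))
  pa <- res$anova$p_value[res$anova$term == "fa"]
  pb <- res$anova$p_value[res$anova$term == "fb"]
  expect_lt(pa, 0.01)
  expect_lt(pb, 0.01)
  expect_true(all(res$tukey$adj_p_value >= 0 & res$tukey$adj_p_value <= 1))
})

test_that("type-I error of the slope comparison is near nominal", {
  set.seed(13)
  doses <- c(0, 2, 4, 8, 12, 16)
  reps <- 400
  rej <- 0
  for (r in seq_len(reps)) {
    fa <- fit_linear(simulate_count_series(1, 0.2, doses, 200))
    fb <- fit_linear(simulate_count_series(1, 0.2, doses, 200))
    if (compare_slopes(fa, fb)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.08)
})
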