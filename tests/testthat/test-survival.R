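test_that("surviving fractions follow the plating-efficiency arithmetic", {
  d <- tibble::tibble(
    dose = c(0, 4), quality = "x", replicate = 1L,
    cells_seeded = c(200L, 500L), colonies_counted = c(100L, 50L)
  )
  sf <- surviving_fractions(d)
  expect_equal(sf$summary$plating_efficiency, c(0.5, 0.5))
  expect_equal(sf$summary$sf[sf$summary$dose == 0], 1)
  expect_equal(sf$summary$sf[sf$summary$dose == 4], 0.2)

  expect_error(surviving_fractions(dplyr::filter(d, dose > 0)), "0 Gy")
  d0 <- dplyr::mutate(d, colonies_counted = c(0L, 0L))
  expect_error(surviving_fractions(d0), "plating efficiency")
})

test_that("simulated surviving fractions match the generating LQ law", {
  p <- survival_truth_params(alpha = 0.3, beta = 0.03,
                             plating_efficiency = 0.5, n_seeded = 1000,
                             doses = c(0, 2, 4, 6, 8), replicates = 10,
                             seed = 21)
  sf <- surviving_fractions(simulate_survival_data(p))
  for (i in seq_len(nrow(sf$summary))) {
    D <- sf$summary$dose[i]
    s_true <- exp(-0.3 * D - 0.03 * D^2)
    prob <- 0.5 * s_true
    se_sf <- sqrt(prob * (1 - prob) / (1000 * 10)) / 0.5
    expect_lt(abs(sf$summary$sf[i] - s_true), 3 * se_sf + 0.02)
  }
})

test_that("LQ fitting recovers exact parameters and respects the boundary", {
  doses <- c(0, 1, 2, 4, 6, 8)
  exact <- tibble::tibble(dose = doses,
                          sf = exp(-0.3 * doses - 0.03 * doses^2))
  fit <- fit_lq(exact)
  expect_lt(abs(fit$alpha - 0.3) / 0.3, 1e-6)
  expect_lt(abs(fit$beta - 0.03) / 0.03, 1e-6)

  pure_exp <- tibble::tibble(dose = doses, sf = exp(-0.25 * doses))
  fe <- fit_lq(pure_exp)
  expect_gte(fe$beta, 0)
  expect_lt(fe$beta, 1e-10)
  expect_equal(fe$alpha, 0.25, tolerance = 1e-8)

  # SF <= 0 rows are excluded with a warning
  with_zero <- dplyr::mutate(exact, sf = ifelse(dose == 8, 0, sf))
  expect_warning(fz <- fit_lq(with_zero), "excluded")
  expect_equal(fz$alpha, 0.3, tolerance = 1e-6)

  expect_error(fit_lq(exact[1:3, ]), "3 distinct positive doses")
})

test_that("stochastic LQ recovery is within 3 SE of truth", {
  p <- survival_truth_params(alpha = 0.3, beta = 0.03, n_seeded = 800,
                             doses = c(0, 1, 2, 4, 6, 8), replicates = 3,
                             seed = 33)
  sf <- surviving_fractions(simulate_survival_data(p))
  fit <- fit_lq(sf$summary)
  expect_lt(abs(fit$alpha - 0.3), 3 * max(fit$se["alpha"], 0.05, na.rm = TRUE))
  expect_lt(abs(fit$beta - 0.03), 3 * max(fit$se["beta"], 0.01, na.rm = TRUE))
})

test_that("iso-survival doses solve the LQ equation", {
  fit <- structure(list(alpha = 0.3, beta = 0.03), class = "lq_fit")
  d10 <- dose_at_survival(fit, 0.1)
  # independent quadratic-root oracle
  oracle <- (-0.3 + sqrt(0.3^2 - 4 * 0.03 * log(0.1))) / (2 * 0.03)
  expect_equal(d10, oracle, tolerance = 1e-12)
  expect_equal(exp(-0.3 * d10 - 0.03 * d10^2), 0.1, tolerance = 1e-12)

  lin <- structure(list(alpha = log(10) / 10, beta = 0), class = "lq_fit")
  expect_equal(dose_at_survival(lin, 0.1), 10, tolerance = 1e-12)

  expect_equal(dose_at_survival(fit, 1), 0)

  # strictly decreasing in the survival level
  levels <- c(0.8, 0.5, 0.2, 0.1, 0.01)
  ds <- vapply(levels, function(l) dose_at_survival(fit, l), numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("RBE is the iso-survival dose ratio", {
  ref <- structure(list(alpha = log(10) / 10, beta = 0), class = "lq_fit")
  tst <- structure(list(alpha = log(10) / 5, beta = 0), class = "lq_fit")
  expect_equal(rbe(ref, tst, 0.1), 2, tolerance = 1e-12)
  expect_equal(rbe(ref, ref, 0.1), 1)
  expect_equal(rbe(tst, tst, 0.37), 1)
})
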