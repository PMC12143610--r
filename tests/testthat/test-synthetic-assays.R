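test_that("survival generator matches the LQ law", {
  # no-kill limit: expected colonies = n_seeded * plating_efficiency
  p0 <- survival_truth_params(alpha = 0, beta = 0, plating_efficiency = 0.4,
                              n_seeded = 1000, replicates = 20, seed = 4)
  d0 <- simulate_survival_data(p0)
  expect_equal(nrow(d0), length(p0$doses) * 20)
  for (d in p0$doses) {
    m <- mean(d0$colonies_counted[d0$dose == d])
    se <- sqrt(1000 * 0.4 * 0.6 / 20)
    expect_lt(abs(m - 400), 3 * se)
  }

  # closed form: alpha=0.3, beta=0.03 at D=2 -> E[S] = exp(-0.72)
  p <- survival_truth_params(alpha = 0.3, beta = 0.03,
                             plating_efficiency = 0.5, n_seeded = 2000,
                             doses = c(0, 2), replicates = 30, seed = 5)
  d <- simulate_survival_data(p)
  prob2 <- 0.5 * exp(-0.72)
  m2 <- mean(d$colonies_counted[d$dose == 2]) / 2000
  expect_lt(abs(m2 - prob2), 3 * sqrt(prob2 * (1 - prob2) / (2000 * 30)))

  # shape and determinism
  p3 <- survival_truth_params(replicates = 3, seed = 6)
  d3 <- simulate_survival_data(p3)
  expect_true(all(table(d3$dose) == 3))
  expect_identical(d3, simulate_survival_data(p3))

  expect_error(survival_truth_params(doses = c(1, 2, 4)), "0 Gy")
})

test_that("Cq generator round-trips fold changes and is deterministic", {
  fc <- tibble::tibble(gene = "Ifnb1", condition = "irr", fold_change = 2)
  tab <- simulate_cq_table(fc, conditions = c("ctrl", "irr"),
                           cq_noise_sd = 0, seed = 3)
  r <- delta_delta_ct(tab, "Ifnb1", "irr", "ctrl")
  expect_equal(r$fold_change, 2)

  # fold change 1 -> identical Cq across conditions for that gene
  fc1 <- tibble::tibble(gene = "Trex1", condition = "irr", fold_change = 1)
  tab1 <- simulate_cq_table(fc1, conditions = c("ctrl", "irr"),
                            cq_noise_sd = 0, seed = 3)
  cqs <- tab1 |>
    dplyr::filter(gene == "Trex1") |>
    dplyr::distinct(condition, cq)
  expect_equal(length(unique(cqs$cq)), 1L)

  tab_a <- simulate_cq_table(fc, conditions = c("ctrl", "irr"), seed = 8)
  tab_b <- simulate_cq_table(fc, conditions = c("ctrl", "irr"), seed = 8)
  expect_identical(tab_a, tab_b)

  expect_error(
    simulate_cq_table(fc, conditions = c("ctrl", "irr"),
                      reference_genes = "Gapdh"),
    "2 reference genes"
  )
})

test_that("expression-matrix generator plants the stated effects", {
  # no DE planted -> all truth labels negative
  em0 <- simulate_expression_matrix(
    expression_truth_params(de_fraction = 0, seed = 2)
  )
  expect_false(any(em0$truth$is_de))

  # shape contract
  em <- simulate_expression_matrix(
    expression_truth_params(n_genes = 3, groups = c(a = 3L, b = 3L), seed = 2)
  )
  expect_equal(dim(em$fpkm), c(3L, 6L))

  # vanishing noise: realized group-mean ratio -> 2 for log2FC = 1
  emv <- simulate_expression_matrix(
    expression_truth_params(log2fc = 1, noise_sdlog = 1e-9, seed = 7)
  )
  up <- which(emv$truth$direction == "up")
  ratio <- rowMeans(emv$fpkm[up, 4:6, drop = FALSE]) /
    rowMeans(emv$fpkm[up, 1:3, drop = FALSE])
  expect_equal(ratio, rep(2, length(up)), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(expression_truth_params(sdlog = 0), "positive")
})
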