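cq_fixture <- function() {
  tibble::tibble(
    condition = rep(c("treated", "control"), each = 3),
    gene = rep(c("Ifnb1", "Gapdh", "Rpl13a"), 2),
    cq = c(24, 19, 21, 26, 20, 22)
  )
}

test_that("ddCt reproduces the mixed-reference hand calculation", {
  r <- delta_delta_ct(cq_fixture(), "Ifnb1", "treated", "control")
  # independent hand oracle: geometric means sqrt(19*21) and sqrt(20*22)
  ddct_hand <- (24 - sqrt(399)) - (26 - sqrt(440))
  expect_lt(abs(r$ddct - ddct_hand), 1e-9)
  expect_lt(abs(r$fold_change - 2^(-ddct_hand)), 1e-9)
})

test_that("ddCt basic identities hold", {
  tab <- cq_fixture()
  self <- delta_delta_ct(tab, "Ifnb1", "control", "control")
  expect_equal(self$fold_change, 1)

  # one cycle lower in treated with identical references -> fold change 2
  tab2 <- tibble::tibble(
    condition = rep(c("t", "c"), each = 3),
    gene = rep(c("g", "Gapdh", "Rpl13a"), 2),
    cq = c(25, 20, 22, 26, 20, 22)
  )
  expect_equal(delta_delta_ct(tab2, "g", "t", "c")$fold_change, 2)

  expect_error(
    delta_delta_ct(tab, "Ifnb1", "treated", "control",
                   reference_genes = "Gapdh"),
    "2 reference genes"
  )
  expect_error(delta_delta_ct(tab, "Trex1", "treated", "control"), "missing")
})

test_that("ddCt invariances: global Cq shift and reference swap", {
  tab <- cq_fixture()
  base <- delta_delta_ct(tab, "Ifnb1", "treated", "control")
  shifted <- dplyr::mutate(tab, cq = cq + 3.7)

  # with condition-dependent reference Cqs, only the arithmetic reference
  # mean is exactly shift-equivariant; the geometric-of-Cq convention is
  # invariant to ~1e-3 here and exactly invariant when references are stable
  base_ar <- delta_delta_ct(tab, "Ifnb1", "treated", "control",
                            reference_mean = "arithmetic")
  rs_ar <- delta_delta_ct(shifted, "Ifnb1", "treated", "control",
                          reference_mean = "arithmetic")
  expect_equal(rs_ar$fold_change, base_ar$fold_change, tolerance = 1e-12)
  rs_geo <- delta_delta_ct(shifted, "Ifnb1", "treated", "control")
  expect_equal(rs_geo$fold_change, base$fold_change, tolerance = 1e-3)

  stable <- dplyr::mutate(
    tab, cq = ifelse(gene == "Gapdh", 20, ifelse(gene == "Rpl13a", 22, cq))
  )
  b0 <- delta_delta_ct(stable, "Ifnb1", "treated", "control")
  b1 <- delta_delta_ct(dplyr::mutate(stable, cq = cq + 3.7),
                       "Ifnb1", "treated", "control")
  expect_equal(b1$fold_change, b0$fold_change, tolerance = 1e-14)

  swapped <- delta_delta_ct(tab, "Ifnb1", "treated", "control",
                            reference_genes = c("Rpl13a", "Gapdh"))
  expect_equal(swapped$ddct, base$ddct, tolerance = 1e-12)
})

test_that("reference stability flags shifted references", {
  stable <- tibble::tibble(
    condition = rep(c("a", "b", "c"), each = 2),
    gene = rep(c("Gapdh", "Rpl13a"), 3),
    cq = rep(c(20, 22), 3)
  )
  r <- reference_stability(stable)
  expect_equal(r$sd_cq, c(0, 0))
  expect_false(any(r$flagged))

  shifted <- dplyr::mutate(stable,
                           cq = ifelse(condition == "c" & gene == "Gapdh",
                                       cq + 2, cq))
  r2 <- reference_stability(shifted)
  expect_true(r2$flagged[r2$gene == "Gapdh"])
  expect_false(r2$flagged[r2$gene == "Rpl13a"])

  one <- dplyr::filter(stable, condition == "a")
  expect_error(reference_stability(one), "2 conditions")

  # noisy table: mean reported SD tracks the generating noise (the sample SD
  # of 3 values has expectation c4(3) * sigma ~ 0.886 * 0.2)
  set.seed(4)
  reps <- replicate(300, {
    noisy <- dplyr::mutate(stable, cq = cq + rnorm(6, 0, 0.2))
    reference_stability(noisy)$sd_cq
  })
  expect_lt(abs(mean(reps) - 0.2 * 0.8862), 0.02)
})

test_that("DE filter applies the three inclusive criteria", {
  groups <- c(a1 = "a", a2 = "a", a3 = "a", b1 = "b", b2 = "b", b3 = "b")
  m <- rbind(
    low = c(0.1, 0.12, 0.11, 0.4, 0.42, 0.41),   # both means < 0.5
    fc_edge = c(2, 2, 2, 3, 3, 3),                # FC exactly 1.5
    floor_edge = c(0.5, 0.5, 0.5, 0.1, 0.1, 0.1), # mean exactly 0.5 in a
    null = c(5, 5.1, 4.9, 5.05, 4.95, 5)          # no effect
  )
  colnames(m) <- names(groups)
  res <- de_filter(m, groups, "a", "b")

  expect_false(res$de[res$gene == "low"])
  expect_false(res$passes_fpkm[res$gene == "low"])

  edge <- res[res$gene == "fc_edge", ]
  expect_equal(edge$fold_change, 1.5, ignore_attr = TRUE)
  expect_true(edge$passes_fc)
  expect_true(edge$de)

  fl <- res[res$gene == "floor_edge", ]
  expect_true(fl$passes_fpkm)
  expect_true(fl$de)
  expect_equal(fl$direction, "down")

  expect_false(res$de[res$gene == "null"])

  expect_error(de_filter(m[, 1:3], groups[1:3], "a", "b"), "at least 2")
})

test_that("DE filter is invariant to gene and sample order", {
  em <- simulate_expression_matrix(expression_truth_params(seed = 8))
  base <- de_filter(em$fpkm, em$groups, "control", "irradiated")
  perm_g <- sample(nrow(em$fpkm))
  perm_s <- c(sample(1:3), sample(4:6))
  shuffled <- de_filter(em$fpkm[perm_g, perm_s], em$groups[perm_s],
                        "control", "irradiated")
  expect_equal(dplyr::arrange(shuffled, gene), dplyr::arrange(base, gene))
})

test_that("Z-score rows are standardized and constant rows flagged", {
  z1 <- zscore_matrix(matrix(c(1, 2, 3), 1, 3))
  expect_equal(mean(z1$z), 0)
  expect_equal(sd(z1$z), 1)

  zc <- zscore_matrix(matrix(5, 2, 4))
  expect_true(all(zc$z == 0))
  expect_true(all(zc$constant))

  set.seed(6)
  m <- matrix(rnorm(150), 30, 5)
  z <- zscore_matrix(m)$z
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))

  expect_error(zscore_matrix(matrix(1, 3, 1)), "2 conditions")
})
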