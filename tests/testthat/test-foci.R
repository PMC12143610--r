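test_that("signal detection finds planted components exactly on clean images", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(detect_dsdna_signals(blank, threshold = 10)), 0L)

  img <- matrix(0, 64, 64)
  off <- cytofoci:::disk_offsets(7)
  img[cbind(30 + off$dr, 40 + off$dc)] <- 500
  comp <- detect_dsdna_signals(img, threshold = 100)
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$area, 7L)
  expect_equal(comp$row, mean(30 + off$dr))
  expect_equal(comp$col, mean(40 + off$dc))
})

test_that("diagonal pixel chains form one component under 8-connectivity", {
  m <- matrix(0, 10, 10)
  m[cbind(2:5, 2:5)] <- 1
  expect_equal(max(label_components(m)), 1L)
  expect_equal(max(label_components(m, connectivity = 4)), 4L)
})

test_that("size and compartment rules accept and reject as declared", {
  seg <- toy_segmentation()
  comps <- toy_components(list(
    block_px(6, 6, 3, 6),          # 4 px inside cytoplasm of cell 1
    c(block_px(6, 6, 3, 6), block_px(7, 7, 3, 3)),  # 5 px, same place
    block_px(10, 12, 7, 10),       # 12 px overlapping nucleus 1
    block_px(2, 3, 27, 29),        # 6 px outside any territory
    block_px(6, 8, 17, 20)         # 12 px inside cytoplasm of cell 2
  ))
  foci <- filter_cytoplasmic_foci(comps, seg, min_area = 5)
  expect_equal(foci$reason,
               c("too_small", NA, "in_nucleus", "outside_cytoplasm", NA))
  expect_equal(foci$accepted, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(foci$cell, c(NA, 1L, NA, NA, 2L))

  expect_error(filter_cytoplasmic_foci(comps, seg, min_area = 0), "min_area")
})

test_that("per-cell counting includes zero-count cells and validates ids", {
  seg <- toy_segmentation()
  foci <- tibble::tibble(
    focus = 1:3, cell = c(1L, 1L, 2L), area = c(6L, 7L, 8L),
    row = 1, col = 1, accepted = TRUE, reason = NA_character_,
    pixels = list(1L, 2L, 3L)
  )
  tab <- count_foci_per_cell(foci, seg, dose = 8, quality = "xray")
  expect_equal(tab$foci, c(2L, 1L))

  none <- foci[0, ]
  tab0 <- count_foci_per_cell(none, seg)
  expect_equal(tab0$foci, c(0L, 0L))

  bad <- dplyr::mutate(foci, cell = c(1L, 9L, 2L))
  expect_error(count_foci_per_cell(bad, seg), "unknown cell")
})

test_that("background correction subtracts each quality's own 0 Gy mean", {
  tab <- tibble::tibble(
    dose = c(0, 0, 8, 8, 0, 0, 8, 8),
    quality = rep(c("x", "c"), each = 4),
    foci = c(1L, 3L, 6L, 7L, 2L, 4L, 10L, 12L)
  )
  out <- background_correct(tab)
  x8 <- out$corrected_mean[out$quality == "x" & out$dose == 8]
  expect_equal(x8, 6.5 - 2.0)
  expect_equal(out$corrected_mean[out$dose == 0], c(0, 0))
  c8 <- out$corrected_mean[out$quality == "c" & out$dose == 8]
  expect_equal(c8, 11 - 3)

  expect_error(background_correct(dplyr::filter(tab, dose > 0)), "0 Gy")
})

test_that("raising min_area never increases any cell's count", {
  p <- imaging_truth_params(n_cells = 4, seed = 31, image_shape = c(224L, 224L))
  sim <- simulate_field(p, dose = 12)
  seg <- segment_field(sim$field)
  comp <- detect_dsdna_signals(sim$field$dsdna)
  prev <- NULL
  for (a in c(1, 3, 5, 8, 12)) {
    foci <- filter_cytoplasmic_foci(comp, seg, min_area = a)
    counts <- count_foci_per_cell(foci, seg, exclude_border = FALSE)$foci
    if (!is.null(prev)) expect_true(all(counts <= prev))
    prev <- counts
  }
})

test_that("full-chain counts equal ground truth on clean fields", {
  p <- clean_params(n_cells = 4, seed = 23, nuclear_focus_rate = 0.5)
  for (i in 1:3) {
    sim <- simulate_field(p, dose = 8, index = i)
    seg <- segment_field(sim$field)
    comp <- detect_dsdna_signals(sim$field$dsdna)
    foci <- filter_cytoplasmic_foci(comp, seg)
    tab <- count_foci_per_cell(foci, seg, exclude_border = FALSE)
    lab_of <- truth_to_seg_cells(sim$truth, seg)
    want <- vapply(sort(unique(sim$truth$cells$cell)), function(tc) {
      sum(sim$truth$foci$compartment == "cytoplasmic" &
            sim$truth$foci$area >= 5 & sim$truth$foci$cell == tc)
    }, numeric(1))
    expect_equal(tab$foci[match(lab_of, tab$cell)], want,
                 ignore_attr = TRUE)
  }
})
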