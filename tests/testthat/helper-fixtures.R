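# Shared fixtures, built in code.

# Clean (noise-free, blur-free) imaging parameters for exactness fixtures.
clean_params <- function(n_cells = 4, seed = 1L,
                         image_shape = c(224L, 224L), ...) {
  imaging_truth_params(
    n_cells = n_cells, noise_sd = 0, psf_sigma = 0, seed = seed,
    image_shape = image_shape, ...
  )
}

# Map ground-truth cell ids to segmentation labels via nucleus overlap.
truth_to_seg_cells <- function(truth, seg) {
  vapply(sort(unique(truth$cells$cell)), function(tc) {
    px <- which(truth$nucleus_labels == tc)
    labs <- seg$nucleus_labels[px]
    labs <- labs[labs > 0L]
    if (!length(labs)) return(NA_integer_)
    as.integer(names(which.max(table(labs))))
  }, integer(1))
}

# A hand-built segmentation object: two 10x10 cells side by side in a 20x30
# image, nucleus = central 4x4 block of each cell.
toy_segmentation <- function() {
  nuc <- matrix(0L, 20, 30)
  cyto <- matrix(0L, 20, 30)
  nuc[9:12, 5:8] <- 1L
  nuc[9:12, 19:22] <- 2L
  cyto[5:16, 2:11] <- 1L
  cyto[5:16, 16:25] <- 2L
  cyto[nuc > 0L] <- 0L
  structure(
    list(
      nucleus_labels = nuc, cytoplasm_labels = cyto,
      cells = tibble::tibble(
        cell = c(1L, 2L),
        nucleus_area = c(16L, 16L),
        cytoplasm_area = c(sum(cyto == 1L), sum(cyto == 2L)),
        touches_border = c(FALSE, FALSE)
      )
    ),
    class = "segmentation"
  )
}

# Build a components tibble from a list of pixel-index vectors on a given
# image dimension (as detect_dsdna_signals would return).
toy_components <- function(pixel_sets, dim_img = c(20L, 30L)) {
  nr <- dim_img[1]
  rows <- lapply(pixel_sets, function(px) ((px - 1L) %% nr) + 1L)
  cols <- lapply(pixel_sets, function(px) ((px - 1L) %/% nr) + 1L)
  out <- tibble::tibble(
    component = seq_along(pixel_sets),
    area = lengths(pixel_sets),
    row = vapply(rows, mean, numeric(1)),
    col = vapply(cols, mean, numeric(1)),
    pixels = pixel_sets
  )
  attr(out, "image_dim") <- dim_img
  out
}

# Linear pixel indices for a block [r1:r2, c1:c2] on an nr-row image.
block_px <- function(r1, r2, c1, c2, nr = 20L) {
  as.integer(outer(r1:r2, (c1:c2 - 1L) * nr, `+`))
}

# Per-dose mean focus-count series simulated directly from the Poisson
# ground-truth model (no imaging), as used for slope-recovery Monte Carlo.
simulate_count_series <- function(intercept, slope, doses, n_cells) {
  purrr::map_dfr(doses, function(d) {
    x <- rpois(n_cells, intercept + slope * d)
    tibble::tibble(dose = d, response = mean(x),
                   se = sd(x) / sqrt(n_cells), n = n_cells)
  })
}
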