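#' Parameters for the synthetic microscopy field generator
#'
#' Bundles the ground-truth parameters used by [simulate_field()]. Cells are
#' drawn as an elliptical nucleus surrounded by a cytoplasmic territory; the
#' expected number of planted cytoplasmic dsDNA foci per cell follows a
#' linear dose response `b + s * dose`, with `b` the 0 Gy background rate and
#' `s` the radiation-quality-specific induction slope (foci/cell/Gy). The
#' nuclear dsDNA signal is rendered at `nuclear_saturation_level`, emulating
#' exposure settings optimized for the dim cytosolic signal that overexpose
#' the nucleus.
#'
#' @param n_cells Cells per field.
#' @param nucleus_radii Length-2 numeric, semi-major/semi-minor nucleus axes
#'   in pixels.
#' @param cytoplasm_margin Width in pixels of the cytoplasmic ring beyond the
#'   nucleus ellipse.
#' @param focus_rate_intercept Mean planted cytoplasmic foci per cell at
#'   0 Gy (the background rate `b`). The background rate of real cells is not
#'   pinned by any reference; this default is a plain modelling choice and
#'   should be set by the user when emulating a specific dataset.
#' @param focus_rate_slope Mean additional foci per cell per Gy (`s`).
#' @param focus_area Length-2 integer range; each planted focus gets a pixel
#'   area drawn uniformly from this range, so the >= 5 px calling threshold
#'   is exercised from both sides with the default.
#' @param focus_intensity Peak intensity of a planted focus before blur
#'   (exposure is assumed optimized for the dim cytosolic signal, so foci sit
#'   well above background).
#' @param background_level Camera dark-offset added to every channel, in
#'   intensity units; keeps the additive noise off the zero clip as on a real
#'   sensor.
#' @param psf_sigma Gaussian blur sigma in pixels (0 disables blur; use 0 for
#'   noise-free oracle fixtures).
#' @param noise_sd Additive Gaussian read-noise SD in intensity units.
#' @param nuclear_saturation_level Intensity at which the nuclear area is
#'   rendered in the dsDNA channel (0 disables the nuclear signal). The
#'   default equals the 12-bit sensor maximum, i.e. a saturated nucleus.
#' @param nuclear_focus_rate Mean planted nucleus-overlapping dsDNA blobs per
#'   cell; these carry compartment label `"nuclear"` in the ground truth and
#'   must be rejected by the compartment rule downstream.
#' @param image_shape Length-2 integer, field size in pixels (rows, cols).
#' @param bit_depth Sensor bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param seed Integer seed; field `index` is mixed in so each field has its
#'   own deterministic substream.
#' @return A list of class `imaging_truth_params`.
#' @export
imaging_truth_params <- function(n_cells = 6,
                                 nucleus_radii = c(14, 10),
                                 cytoplasm_margin = 12,
                                 focus_rate_intercept = 1,
                                 focus_rate_slope = 0.2,
                                 focus_area = c(3L, 12L),
                                 focus_intensity = 2000,
                                 background_level = 100,
                                 psf_sigma = 1,
                                 noise_sd = 50,
                                 nuclear_saturation_level = 4095,
                                 nuclear_focus_rate = 0,
                                 image_shape = c(256L, 256L),
                                 bit_depth = 12,
                                 seed = 1L) {
  stopifnot(
    n_cells >= 0,
    focus_rate_intercept >= 0,
    focus_rate_slope >= 0,
    length(focus_area) == 2L, focus_area[1] >= 1, focus_area[2] >= focus_area[1],
    length(nucleus_radii) == 2L, all(nucleus_radii > 0),
    cytoplasm_margin >= 1,
    noise_sd >= 0, psf_sigma >= 0, background_level >= 0,
    nuclear_focus_rate >= 0,
    length(image_shape) == 2L, all(image_shape >= 16)
  )
  structure(
    list(
      n_cells = as.integer(n_cells),
      nucleus_radii = as.numeric(nucleus_radii),
      cytoplasm_margin = as.numeric(cytoplasm_margin),
      focus_rate_intercept = focus_rate_intercept,
      focus_rate_slope = focus_rate_slope,
      focus_area = as.integer(focus_area),
      focus_intensity = focus_intensity,
      background_level = background_level,
      psf_sigma = psf_sigma,
      noise_sd = noise_sd,
      nuclear_saturation_level = nuclear_saturation_level,
      nuclear_focus_rate = nuclear_focus_rate,
      image_shape = as.integer(image_shape),
      bit_depth = bit_depth,
      seed = as.integer(seed)
    ),
    class = "imaging_truth_params"
  )
}

#' Simulate one ground-truthed microscopy field
#'
#' Generates the three registered channels of a field of view (dsDNA
#' immunostain, nucleus stain, cytoplasm stain) together with exact ground
#' truth: per-cell nucleus and territory label masks and a table of planted
#' dsDNA foci (centroid, pixel area, owning cell, compartment). Planted
#' cytoplasmic foci lie fully inside their cell's cytoplasmic ring and
#' outside its nucleus by construction; planted "nuclear" blobs overlap the
#' nucleus. Foci counts per cell are Poisson with mean
#' `focus_rate_intercept + focus_rate_slope * dose`.
#'
#' The same `(params, dose, quality, index)` always yields bit-identical
#' output: the field index is mixed into `params$seed` to derive a
#' deterministic per-field substream.
#'
#' @param params An [imaging_truth_params()] object.
#' @param dose Physical dose in Gy (>= 0).
#' @param quality Radiation-quality tag (e.g. `"xray"`, `"carbon"`).
#' @param index Field index within the experiment (drives the substream).
#' @return A list with elements `field` (class `fov`: matrices `dsdna`,
#'   `nucleus_stain`, `cytoplasm_stain` plus metadata) and `truth` (class
#'   `field_truth`: `nucleus_labels`, `cytoplasm_labels`, tibbles `cells` and
#'   `foci`).
#' @export
simulate_field <- function(params, dose, quality = "xray", index = 1L) {
  stopifnot(inherits(params, "imaging_truth_params"), dose >= 0)
  with_seed(mix_seed(params$seed, index), {
    nr <- params$image_shape[1]
    nc <- params$image_shape[2]
    a_nuc <- params$nucleus_radii[1]
    b_nuc <- params$nucleus_radii[2]
    a_env <- a_nuc + params$cytoplasm_margin
    b_env <- b_nuc + params$cytoplasm_margin

    nucleus_labels <- matrix(0L, nr, nc)
    cyto_labels <- matrix(0L, nr, nc)
    occupied <- matrix(FALSE, nr, nc)
    cells <- list()

    # non-overlapping placement by rejection sampling, bounded retries
    for (cell in seq_len(params$n_cells)) {
      placed <- FALSE
      for (try in seq_len(300L)) {
        theta <- runif(1, 0, pi)
        margin <- ceiling(max(a_env, b_env)) + 2
        if (nr - margin <= margin || nc - margin <= margin) {
          abort("image_shape too small for the requested cell geometry")
        }
        cr <- runif(1, margin, nr - margin)
        cc <- runif(1, margin, nc - margin)
        env <- ellipse_mask(nr, nc, cr, cc, a_env + 1, b_env + 1, theta)
        if (!any(env & occupied)) {
          nuc <- ellipse_mask(nr, nc, cr, cc, a_nuc, b_nuc, theta)
          ring <- ellipse_mask(nr, nc, cr, cc, a_env, b_env, theta) & !nuc
          nucleus_labels[nuc] <- cell
          cyto_labels[ring] <- cell
          occupied <- occupied | env
          cells[[cell]] <- tibble::tibble(
            cell = cell, centre_row = cr, centre_col = cc, theta = theta,
            nucleus_area = sum(nuc), cytoplasm_area = sum(ring)
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0(
          "could not place cell ", cell, " of ", params$n_cells,
          " without overlap after 300 attempts; enlarge image_shape or ",
          "reduce n_cells/cell size"
        ))
      }
    }
    cells <- if (length(cells)) dplyr::bind_rows(cells) else tibble::tibble(
      cell = integer(), centre_row = numeric(), centre_col = numeric(),
      theta = numeric(), nucleus_area = integer(), cytoplasm_area = integer()
    )

    # plant foci; keep plants apart so fixtures never merge two plants into
    # one connected component
    foci_img <- matrix(0, nr, nc)
    forbidden <- matrix(FALSE, nr, nc)
    foci <- list()
    fid <- 0L
    lambda_cyto <- params$focus_rate_intercept + params$focus_rate_slope * dose
    box <- function(r) EBImage::makeBrush(2L * r + 1L, "box")
    for (cell in seq_len(params$n_cells)) {
      # placement region for cytoplasmic plants: inside the cell's ring with
      # 2 px clearance from the ring edge and 5 px from the nucleus, so a
      # blurred focus neither leaves the territory nor bridges into the
      # saturated nuclear blob
      ring <- cyto_labels == cell
      nucm <- nucleus_labels == cell
      allowed <- matrix(
        as.logical(EBImage::erode(ring * 1, box(2L))) &
          !as.logical(EBImage::dilate(nucm * 1, box(5L))),
        nr, nc
      )
      n_cyto <- rpois(1, lambda_cyto)
      n_nuc <- if (params$nuclear_focus_rate > 0) rpois(1, params$nuclear_focus_rate) else 0L
      for (k in seq_len(n_cyto + n_nuc)) {
        compartment <- if (k <= n_cyto) "cytoplasmic" else "nuclear"
        area <- sample(params$focus_area[1]:params$focus_area[2], 1)
        off <- disk_offsets(area)
        cand <- which(if (compartment == "cytoplasmic") allowed else nucm,
                      arr.ind = TRUE)
        if (nrow(cand) == 0L) next
        ok <- FALSE
        for (try in seq_len(100L)) {
          ctr <- cand[sample.int(nrow(cand), 1), ]
          rows <- ctr[1] + off$dr
          cols <- ctr[2] + off$dc
          if (any(rows < 1 | rows > nr | cols < 1 | cols > nc)) next
          idx <- cbind(rows, cols)
          inside <- if (compartment == "cytoplasmic") {
            all(allowed[idx])
          } else {
            any(nucleus_labels[idx] == cell)
          }
          if (inside && !any(forbidden[idx])) {
            foci_img[idx] <- params$focus_intensity
            # forbid a 3-px Chebyshev halo around the planted pixels so
            # blurred neighbours never merge into one component
            for (dr in -3:3) for (dc in -3:3) {
              rr <- pmin(pmax(rows + dr, 1), nr)
              cc2 <- pmin(pmax(cols + dc, 1), nc)
              forbidden[cbind(rr, cc2)] <- TRUE
            }
            fid <- fid + 1L
            foci[[fid]] <- tibble::tibble(
              focus = fid, cell = cell, compartment = compartment,
              row = mean(rows), col = mean(cols), area = area
            )
            ok <- TRUE
            break
          }
        }
        # a focus that cannot be placed (crowded cell) is simply skipped;
        # truth reflects what was actually planted
        if (!ok) next
      }
    }
    foci <- if (length(foci)) dplyr::bind_rows(foci) else tibble::tibble(
      focus = integer(), cell = integer(), compartment = character(),
      row = numeric(), col = numeric(), area = integer()
    )

    # render channels
    max_i <- 2^params$bit_depth - 1
    dsdna <- foci_img
    if (params$nuclear_saturation_level > 0) {
      dsdna[nucleus_labels > 0L] <- pmax(
        dsdna[nucleus_labels > 0L], params$nuclear_saturation_level
      )
    }
    nucleus_stain <- matrix(0, nr, nc)
    nucleus_stain[nucleus_labels > 0L] <- 0.75 * max_i
    cytoplasm_stain <- matrix(0, nr, nc)
    cytoplasm_stain[nucleus_labels > 0L | cyto_labels > 0L] <- 0.25 * max_i

    blur <- function(x) {
      if (params$psf_sigma > 0) {
        matrix(as.numeric(EBImage::gblur(x, sigma = params$psf_sigma)), nr, nc)
      } else {
        x
      }
    }
    add_noise <- function(x) {
      x <- x + params$background_level
      if (params$noise_sd > 0) x + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc) else x
    }
    clip <- function(x) pmin(pmax(x, 0), max_i)

    field <- structure(
      list(
        dsdna = clip(add_noise(blur(dsdna))),
        nucleus_stain = clip(add_noise(blur(nucleus_stain))),
        cytoplasm_stain = clip(add_noise(blur(cytoplasm_stain))),
        field_id = index, dose = dose, quality = quality,
        bit_depth = params$bit_depth
      ),
      class = "fov"
    )
    truth <- structure(
      list(
        nucleus_labels = nucleus_labels, cytoplasm_labels = cyto_labels,
        cells = cells, foci = foci,
        field_id = index, dose = dose, quality = quality
      ),
      class = "field_truth"
    )
    list(field = field, truth = truth)
  })
}

#' @export
print.fov <- function(x, ...) {
  cat("<fov> field", x$field_id, "-", x$dose, "Gy", x$quality, "-",
      nrow(x$dsdna), "x", ncol(x$dsdna), "px,", x$bit_depth, "bit\n")
  invisible(x)
}

#' @export
print.field_truth <- function(x, ...) {
  cat("<field_truth> field", x$field_id, "-", nrow(x$cells), "cells,",
      nrow(x$foci), "planted foci (",
      sum(x$foci$compartment == "cytoplasmic"), "cytoplasmic )\n")
  invisible(x)
}
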