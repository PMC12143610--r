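# Cytoplasmic dsDNA focus calling.
#
# Detection threshold: background-robust median + k * MAD rather than Otsu,
# because the deliberately overexposed (saturated) nuclei dominate the
# intensity histogram and would drag a bimodal threshold far above the dim
# cytosolic signal. Components are 8-connected. The compartment rule is
# applied afterwards: a signal is a cytoplasmic focus only if it has no
# pixel on a nucleus label and lies inside a cytoplasm territory.

#' Detect candidate dsDNA signals as connected components
#'
#' Thresholds the dsDNA channel at `median + k * MAD` of the whole image and
#' returns every 8-connected component of above-threshold pixels, including
#' the saturated nuclear blobs — the compartment rule of
#' [filter_cytoplasmic_foci()] removes those later.
#'
#' @param dsdna Numeric intensity matrix.
#' @param k MAD multiplier for the global threshold (default 5).
#' @param threshold Optional explicit intensity threshold overriding the
#'   robust rule.
#' @return A tibble with one row per component: `component`, `area` (px),
#'   `row`, `col` (intensity-agnostic pixel centroid) and `pixels` (list
#'   column of linear pixel indices). The source image dimension is attached
#'   as attribute `image_dim`. A blank image yields zero rows.
#' @export
detect_dsdna_signals <- function(dsdna, k = 5, threshold = NULL) {
  stopifnot(is.matrix(dsdna), length(dsdna) > 0)
  th <- threshold %||% (median(dsdna) + k * mad(dsdna))
  lab <- label_components(dsdna > th, connectivity = 8)
  n <- max(lab)
  if (n == 0L) {
    out <- tibble::tibble(component = integer(), area = integer(),
                          row = numeric(), col = numeric(), pixels = list())
  } else {
    idx <- which(lab > 0L)
    id <- lab[idx]
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    out <- tibble::tibble(
      component = seq_len(n),
      area = as.integer(tabulate(id, nbins = n)),
      row = as.numeric(tapply(rows, id, mean)),
      col = as.numeric(tapply(cols, id, mean)),
      pixels = unname(split(idx, id))
    )
  }
  attr(out, "image_dim") <- dim(dsdna)
  out
}

#' Apply the size and compartment rules to candidate dsDNA signals
#'
#' A component is accepted as a cytoplasmic dsDNA focus iff its area is at
#' least `min_area` pixels, no pixel of it overlaps any nucleus label
#' (strict any-overlap rule: the overexposed nuclear signal must never leak
#' into the counts), its centroid lies inside a cytoplasm territory, and at
#' least `min_inside_fraction` of its pixels lie in that territory. Rejected
#' components keep their reason: `too_small`, `in_nucleus`,
#' `outside_cytoplasm` (centroid in no territory) or `unassigned` (centroid
#' in a territory but too few pixels inside it).
#'
#' @param components Tibble from [detect_dsdna_signals()].
#' @param segmentation A `segmentation` object aligned with the components'
#'   source image.
#' @param min_area Minimum focus area in pixels (default 5; must be >= 1).
#' @param min_inside_fraction Minimum fraction of focus pixels inside the
#'   assigned territory (default 0.5).
#' @return A tibble of foci: `focus`, `cell` (NA when rejected before
#'   assignment), `area`, `row`, `col`, `accepted`, `reason` (NA when
#'   accepted) and `pixels`.
#' @export
filter_cytoplasmic_foci <- function(components, segmentation,
                                    min_area = 5,
                                    min_inside_fraction = 0.5) {
  stopifnot(inherits(segmentation, "segmentation"))
  if (min_area < 1) abort("min_area must be >= 1")
  dim_img <- attr(components, "image_dim")
  nuc <- segmentation$nucleus_labels
  cyto <- segmentation$cytoplasm_labels
  if (!is.null(dim_img) && !all(dim_img == dim(nuc))) {
    abort("components and segmentation come from images of different shape")
  }
  n <- nrow(components)
  cell <- rep(NA_integer_, n)
  accepted <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    px <- components$pixels[[i]]
    if (components$area[i] < min_area) {
      reason[i] <- "too_small"
    } else if (any(nuc[px] > 0L)) {
      reason[i] <- "in_nucleus"
    } else {
      ctr <- cyto[round(components$row[i]), round(components$col[i])]
      if (ctr == 0L) {
        reason[i] <- "outside_cytoplasm"
      } else if (mean(cyto[px] == ctr) < min_inside_fraction) {
        reason[i] <- "unassigned"
      } else {
        cell[i] <- as.integer(ctr)
        accepted[i] <- TRUE
      }
    }
  }
  tibble::tibble(
    focus = seq_len(n), cell = cell,
    area = components$area, row = components$row, col = components$col,
    accepted = accepted, reason = reason, pixels = components$pixels
  )
}

#' Count accepted cytoplasmic foci per cell
#'
#' Produces one row per segmented cell — including zero-count cells — with
#' the number of accepted foci assigned to it. Cells whose territory touches
#' the image border are excluded by default (their cytoplasm is truncated,
#' biasing the count).
#'
#' @param foci Tibble from [filter_cytoplasmic_foci()].
#' @param segmentation The matching `segmentation` object.
#' @param field_id,dose,quality Metadata attached to every row.
#' @param exclude_border Drop border-touching cells (default TRUE).
#' @return A tibble `field_id, cell, dose, quality, foci` with one row per
#'   retained cell.
#' @export
count_foci_per_cell <- function(foci, segmentation,
                                field_id = 1L, dose = NA_real_,
                                quality = NA_character_,
                                exclude_border = TRUE) {
  stopifnot(inherits(segmentation, "segmentation"))
  acc <- dplyr::filter(foci, .data$accepted)
  unknown <- setdiff(acc$cell, segmentation$cells$cell)
  if (length(unknown)) {
    abort(paste("accepted focus references unknown cell id:",
                paste(unknown, collapse = ", ")))
  }
  cells <- segmentation$cells
  if (exclude_border) cells <- dplyr::filter(cells, !.data$touches_border)
  counts <- table(factor(acc$cell, levels = cells$cell))
  tibble::tibble(
    field_id = field_id, cell = cells$cell,
    dose = dose, quality = quality,
    foci = as.integer(counts[as.character(cells$cell)])
  )
}

#' Background-correct per-group mean focus counts
#'
#' Summarizes per-cell counts into per-(dose, quality) group means and
#' subtracts, within each radiation quality, the mean count of the 0 Gy
#' (unirradiated background) group. Negative corrected means are reported as
#' computed, not clipped.
#'
#' @param foci_table Tibble of per-cell rows with columns `dose`, `quality`,
#'   `foci` (e.g. from [count_foci_per_cell()]).
#' @return A tibble with one row per (quality, dose): `n_cells`, `mean_foci`,
#'   `sd_foci`, `se_foci`, `corrected_mean`. The 0 Gy group's corrected mean
#'   is 0 exactly.
#' @export
background_correct <- function(foci_table) {
  stopifnot(all(c("dose", "quality", "foci") %in% names(foci_table)))
  groups <- foci_table |>
    dplyr::group_by(.data$quality, .data$dose) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_foci = mean(.data$foci),
      sd_foci = sd(.data$foci),
      se_foci = sd(.data$foci) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  missing0 <- groups |>
    dplyr::group_by(.data$quality) |>
    dplyr::summarise(has0 = any(.data$dose == 0), .groups = "drop") |>
    dplyr::filter(!.data$has0)
  if (nrow(missing0)) {
    abort(paste("no 0 Gy background group for quality:",
                paste(missing0$quality, collapse = ", ")))
  }
  groups |>
    dplyr::group_by(.data$quality) |>
    dplyr::mutate(
      corrected_mean = .data$mean_foci - .data$mean_foci[.data$dose == 0][1]
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$quality, .data$dose)
}

#' Run the full focus-calling chain on one field
#'
#' Segments the field, detects dsDNA signals, applies the size and
#' compartment rules and returns per-cell counts.
#'
#' @param field A `fov` object.
#' @param min_area Minimum focus area in pixels (default 5).
#' @param min_nucleus_area Passed to [segment_nuclei()].
#' @param k MAD multiplier for the dsDNA detection threshold.
#' @param exclude_border Passed to [count_foci_per_cell()].
#' @return Per-cell tibble as from [count_foci_per_cell()].
#' @export
count_field_foci <- function(field, min_area = 5, min_nucleus_area = 50,
                             k = 5, exclude_border = TRUE) {
  stopifnot(inherits(field, "fov"))
  seg <- segment_field(field, min_nucleus_area)
  comp <- detect_dsdna_signals(field$dsdna, k = k)
  foci <- filter_cytoplasmic_foci(comp, seg, min_area = min_area)
  count_foci_per_cell(foci, seg, field_id = field$field_id,
                      dose = field$dose, quality = field$quality,
                      exclude_border = exclude_border)
}
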