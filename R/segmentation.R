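# Nucleus / cytoplasm compartment segmentation.
#
# Masks are thresholded with a global Otsu threshold per channel (the
# exposure-balanced nucleus and cytoplasm stains are strongly bimodal); cell
# territories are obtained by propagating each nucleus seed across the
# thresholded cytoplasm stain, i.e. a nearest-nucleus (seeded watershed
# style) partition, so two adjacent cells split the shared stained region
# and no pixel is assigned twice.

otsu_mask <- function(x) {
  mx <- max(x)
  if (mx <= 0) return(matrix(FALSE, nrow(x), ncol(x)))
  xn <- x / mx
  th <- EBImage::otsu(xn, range = c(0, 1), levels = 256L)
  xn > th
}

#' Segment nuclei from the nucleus-stain channel
#'
#' Thresholds the DAPI-like channel with a global Otsu threshold and labels
#' the resulting components under 8-connectivity. Components smaller than
#' `min_nucleus_area` (debris) are removed. Touching nuclei are not split:
#' two nuclei whose thresholded masks touch become one label (the no-split
#' policy is deliberate; downstream per-cell statistics exclude border and
#' pathological cells rather than guess a split).
#'
#' @param nucleus_stain Numeric intensity matrix.
#' @param min_nucleus_area Minimum component area in pixels (default 50).
#' @param threshold Optional explicit intensity threshold overriding Otsu.
#' @return Integer label matrix; 0 is background. An all-zero image yields an
#'   empty (all-0) mask, not an error.
#' @export
segment_nuclei <- function(nucleus_stain, min_nucleus_area = 50,
                           threshold = NULL) {
  stopifnot(is.matrix(nucleus_stain), length(nucleus_stain) > 0)
  mask <- if (is.null(threshold)) otsu_mask(nucleus_stain) else nucleus_stain > threshold
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(sizes < min_nucleus_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_raster_order(lab)
  }
  lab
}

#' Partition the stained cytoplasm into per-cell territories
#'
#' Each labeled nucleus seeds one territory; seeds are propagated across the
#' Otsu-thresholded cytoplasm stain so that the shared stained region of
#' adjacent cells is split along the nearest-seed boundary. Nucleus pixels
#' are excluded from the returned cytoplasm mask; stained regions not
#' reachable from any nucleus remain unlabeled.
#'
#' @param cytoplasm_stain Numeric intensity matrix (same shape as the nucleus
#'   mask).
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param threshold Optional explicit intensity threshold overriding Otsu.
#' @return A list of class `segmentation`: `nucleus_labels`,
#'   `cytoplasm_labels` (territories, nucleus pixels excluded) and a tibble
#'   `cells` with per-cell `nucleus_area`, `cytoplasm_area` and
#'   `touches_border`.
#' @export
segment_cytoplasm <- function(cytoplasm_stain, nucleus_labels,
                              threshold = NULL) {
  if (!is.matrix(cytoplasm_stain) || !is.matrix(nucleus_labels) ||
      !all(dim(cytoplasm_stain) == dim(nucleus_labels))) {
    abort("cytoplasm_stain and nucleus_labels must be matrices of identical shape")
  }
  mask <- if (is.null(threshold)) otsu_mask(cytoplasm_stain) else cytoplasm_stain > threshold
  nr <- nrow(mask); nc <- ncol(mask)
  if (max(nucleus_labels) == 0L) {
    cyto <- matrix(0L, nr, nc)
  } else {
    # propagation mask includes nucleus pixels so territories stay geodesically
    # connected to their seed even where the cytoplasm stain is dim over the
    # nucleus
    prop <- EBImage::propagate(
      cytoplasm_stain / max(max(cytoplasm_stain), 1),
      seeds = nucleus_labels,
      mask = mask | nucleus_labels > 0L
    )
    cyto <- matrix(as.integer(prop), nr, nc)
    cyto[nucleus_labels > 0L] <- 0L
    cyto[!mask] <- 0L
  }
  ids <- sort(unique(nucleus_labels[nucleus_labels > 0L]))
  border <- matrix(FALSE, nr, nc)
  border[c(1, nr), ] <- TRUE
  border[, c(1, nc)] <- TRUE
  cells <- tibble::tibble(
    cell = as.integer(ids),
    nucleus_area = vapply(ids, function(i) sum(nucleus_labels == i), integer(1)),
    cytoplasm_area = vapply(ids, function(i) sum(cyto == i), integer(1)),
    touches_border = vapply(ids, function(i) {
      any(border[nucleus_labels == i]) || any(border[cyto == i])
    }, logical(1))
  )
  structure(
    list(nucleus_labels = nucleus_labels, cytoplasm_labels = cyto,
         cells = cells),
    class = "segmentation"
  )
}

#' Segment a field of view into nucleus and cytoplasm compartments
#'
#' Convenience wrapper running [segment_nuclei()] on the nucleus-stain
#' channel and [segment_cytoplasm()] on the cytoplasm-stain channel.
#'
#' @param field A `fov` object (see [simulate_field()]).
#' @param min_nucleus_area Passed to [segment_nuclei()].
#' @return A `segmentation` object.
#' @export
segment_field <- function(field, min_nucleus_area = 50) {
  stopifnot(inherits(field, "fov"))
  nuc <- segment_nuclei(field$nucleus_stain, min_nucleus_area)
  segment_cytoplasm(field$cytoplasm_stain, nuc)
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation>", nrow(x$cells), "cells;",
      sum(x$cells$touches_border), "touching the border\n")
  invisible(x)
}
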