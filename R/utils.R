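# Internal helpers: deterministic seed substreams, 8-connected labeling,
# simple raster geometry for the synthetic fields.

#' Derive a child seed from a global seed and a stream index
#'
#' Multiplicative mixing folded into `[0, 2^31 - 1]`, so `set.seed()` always
#' receives a valid 32-bit integer. Used throughout the package to expand one
#' experiment-level seed into per-field and per-stage substreams.
#'
#' @param seed Integer master seed.
#' @param index Integer stream index.
#' @return An integer seed.
#' @export
mix_seed <- function(seed, index) {
  s <- (as.numeric(seed) * 2654435761 + as.numeric(index) * 40503) %% 2147483647
  as.integer(s)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Label connected components of a binary mask
#'
#' Components are labeled under 8-connectivity (edge- or corner-adjacent
#' pixels belong to the same component), the convention used throughout the
#' package for dsDNA signals and nuclei. Labels are renumbered in raster-scan
#' order of each component's first pixel (column-major, matching R matrix
#' storage), so labeling is deterministic.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1L) {
    lab <- merge_diagonal_labels(lab)
  }
  relabel_raster_order(lab)
}

# Union 4-connected labels that touch diagonally, yielding 8-connected
# components. Vectorized over the two diagonal shift directions.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(max(lab))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_pairs <- function(a, b) {
    keep <- a != 0L & b != 0L & a != b
    for (k in which(keep)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  # pixel (i, j) vs (i + 1, j + 1) and (i + 1, j - 1)
  union_pairs(lab[-nr, -nc], lab[-1, -1])
  union_pairs(lab[-nr, -1], lab[-1, -nc])
  roots <- vapply(seq_along(parent), find, integer(1))
  out <- lab
  out[lab > 0L] <- roots[lab[lab > 0L]]
  out
}

# Renumber labels 1..K by the raster-scan (column-major) position of each
# component's first pixel.
relabel_raster_order <- function(lab) {
  ids <- lab[lab > 0L]
  if (length(ids) == 0L) return(lab)
  first_pos <- tapply(which(lab > 0L), ids, min)
  ord <- as.integer(names(sort(first_pos)))
  map <- integer(max(lab))
  map[ord] <- seq_along(ord)
  out <- lab
  out[lab > 0L] <- map[ids]
  out
}

# Logical mask of a filled ellipse centred at (cr, cc) with semi-axes (a, b)
# rotated by theta, on an nr x nc grid.
ellipse_mask <- function(nr, nc, cr, cc, a, b, theta = 0) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- r - cr
  dc <- c - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Pixel offsets (relative row/col) of a roughly circular blob of `area`
# pixels: pixels sorted by distance from the origin, ties broken by raster
# order so a given area always yields the same shape.
disk_offsets <- function(area) {
  stopifnot(area >= 1)
  r_max <- ceiling(sqrt(area / pi)) + 2L
  g <- expand.grid(dr = -r_max:r_max, dc = -r_max:r_max)
  d2 <- g$dr^2 + g$dc^2
  ord <- order(d2, g$dr, g$dc)
  g[ord[seq_len(area)], , drop = FALSE]
}

#' Match detected foci to ground-truth centroids
#'
#' Greedy nearest-pair matching between two centroid tables within
#' `max_dist` pixels, as used to score detection precision and recall
#' against planted foci.
#'
#' @param det,truth Data frames with numeric `row` and `col` columns.
#' @param max_dist Maximum centroid distance (pixels) for a match.
#' @return The number of matched pairs.
#' @export
match_centroids <- function(det, truth, max_dist = 3) {
  if (nrow(det) == 0L || nrow(truth) == 0L) return(0L)
  d <- outer(seq_len(nrow(det)), seq_len(nrow(truth)), function(i, j) {
    sqrt((det$row[i] - truth$row[j])^2 + (det$col[i] - truth$col[j])^2)
  })
  n <- 0L
  repeat {
    if (all(!is.finite(d)) || min(d, na.rm = TRUE) > max_dist) break
    idx <- arrayInd(which.min(d), dim(d))
    n <- n + 1L
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  n
}
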