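## Lesion segmentation utilities: windowed intensity normalization, DICE,
## and the slice-component cleanup / small-lesion exclusion rules applied
## before feature extraction.

#' Window-based intensity normalization
#'
#' Maps voxel values to `[0, 1]` using a display window:
#' `clip((v - (level - width/2)) / width, 0, 1)`. The window center maps to
#' 0.5 and values outside the window saturate at 0 or 1.
#'
#' @param volume numeric array (any shape).
#' @param level window level (center), intensity units.
#' @param width window width, must be > 0.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(volume, level, width) {
  if (!is.numeric(width) || width <= 0) stop("window width must be > 0")
  pmin(pmax((volume - (level - width / 2)) / width, 0), 1)
}

#' Robust per-volume window
#'
#' Computes a window (level, width) from the p1/p99 intensity percentiles,
#' used for phantoms where no scanner windowing exists.
#'
#' @param volume numeric array.
#' @return list with `level` and `width`.
#' @export
robust_window <- function(volume) {
  q <- quantile(volume, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-6
  list(level = (q[1] + q[2]) / 2, width = q[2] - q[1])
}

#' DICE overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks of identical shape.
#' Two empty masks have DICE 1 by convention.
#'
#' @param a,b binary arrays of the same shape.
#' @return numeric in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1.0)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}

## 8-connected 2D component labelling of a logical matrix (two-pass scan
## with union-find).
label_components_2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!m[i, j]) next
      nb <- integer(0)
      if (i > 1L && m[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
      if (j > 1L) {
        if (m[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
        if (i > 1L && m[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
        if (i < nr && m[i + 1L, j - 1L]) nb <- c(nb, lab[i + 1L, j - 1L])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        r <- min(roots)
        lab[i, j] <- r
        for (x in roots) parent[x] <- r
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    idx <- which(lab > 0L)
    lab[idx] <- match(roots[lab[idx]], sort(unique(roots)))
  }
  lab
}

#' Clean a predicted mask and apply the small-lesion exclusion rule
#'
#' Per axial slice (third array dimension), removes 8-connected 2D
#' components with fewer than 20 pixels (partial segmentations too small to
#' carry texture). After cleanup, if the total 3D voxel count is below 50
#' the subject is flagged as excluded, mirroring the cohort inclusion rule;
#' the cleaned mask is returned either way. Both thresholds are strict
#' inequalities: a 20-pixel component is retained and a 50-voxel lesion is
#' included.
#'
#' @param mask binary 3D array.
#' @param min_component_pixels per-slice 2D component floor (default 20).
#' @param min_lesion_voxels 3D exclusion floor (default 50).
#' @return list with the cleaned `mask` and logical `excluded`.
#' @export
postprocess_mask <- function(mask, min_component_pixels = 20L,
                             min_lesion_voxels = 50L) {
  if (!is_binary_array(mask)) stop("mask must be binary")
  out <- mask
  for (z in seq_len(dim(mask)[3])) {
    sl <- mask[, , z] > 0
    if (!any(sl)) next
    lab <- label_components_2d(sl)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_component_pixels)
    if (length(drop)) {
      sl[lab %in% drop] <- FALSE
      out[, , z] <- as.integer(sl)
    }
  }
  list(mask = out, excluded = sum(out > 0) < min_lesion_voxels)
}
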