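#' Threshold a probability map at a percentile of its non-zero intensities
#'
#' The cutoff is the type-7 (linear interpolation) quantile of the strictly
#' positive voxel values at percentile `p`; voxels with value `>= cutoff`
#' form the connectivity-based target. Thresholds are scale-free: scaling
#' the map by any positive constant leaves the CBT unchanged.
#'
#' @param map a `thala_volume` probability/count map (or a `thala_cmap`,
#'   which is rendered with [cmap_volume()] first), with at least one
#'   strictly positive voxel.
#' @param percentile percentile in `[50, 100]`.
#' @param intent optional label describing the anatomical intent
#'   (`"vlpv"`, `"precentral"`, `"postcentral"`, `"ctt"`, ...).
#' @return a `thala_cbt`: binary `thala_volume` with attributes
#'   `percentile`, `intent`, `cutoff` and `n_voxels`.
#' @export
percentile_threshold <- function(map, percentile, intent = NA_character_) {
  if (inherits(map, "thala_cmap")) map <- cmap_volume(map)
  stopifnot(percentile >= 50, percentile <= 100)
  vals <- map$data[map$data > 0]
  if (length(vals) == 0) stop("all-zero map: cannot threshold")
  cutoff <- stats::quantile(vals, percentile / 100, type = 7, names = FALSE)
  keep <- map$data >= cutoff
  cbt <- volume(array(keep, dim(map$data)), affine = map$affine)
  cbt$percentile <- percentile
  cbt$intent <- intent
  cbt$cutoff <- cutoff
  cbt$n_voxels <- sum(cbt$data)
  cbt$weight_data <- map$data * keep  # source intensities of kept voxels
  class(cbt) <- c("thala_cbt", class(cbt))
  cbt
}

#' @export
print.thala_cbt <- function(x, ...) {
  cat(sprintf("<thala_cbt> %s: %d voxels at p%.0f (cutoff %s)\n",
              if (is.na(x$intent)) "unnamed" else x$intent,
              x$n_voxels, x$percentile, format(x$cutoff, digits = 4)))
  invisible(x)
}

as_binary_array <- function(x) {
  if (inherits(x, "thala_volume")) x$data != 0 else x != 0
}

#' Dice overlap coefficient
#'
#' `D = 2 |X intersect Y| / (|X| + |Y|)` on the voxel sets of a common
#' grid. `D = 1` iff the sets are identical, 0 iff disjoint.
#'
#' @param x,y binary `thala_volume`s (or logical/numeric arrays) on the
#'   same grid; not both empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(x, y) {
  if (inherits(x, "thala_volume") && inherits(y, "thala_volume") &&
      !same_grid(x, y))
    stop("grid mismatch between the two volumes")
  a <- as_binary_array(x)
  b <- as_binary_array(y)
  if (!identical(dim(a), dim(b))) stop("grid mismatch between the two volumes")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("both volumes are empty")
  2 * sum(a & b) / (na + nb)
}

#' Centre of gravity of a volume, in world mm
#'
#' Binary masks give the unweighted centroid of their voxels; non-binary
#' maps give the intensity-weighted centroid of their positive voxels.
#'
#' @param x a `thala_volume`. A `thala_cbt` defaults to the intensity-
#'   weighted centroid over its surviving voxels, using the source-map
#'   values recorded at thresholding time.
#' @param weighted use intensity weighting (default: yes for non-binary
#'   input and for CBTs; pass `FALSE` for a purely binary centroid).
#' @return length-3 world-mm coordinate.
#' @export
center_of_gravity <- function(x, weighted = NULL) {
  vals <- as.numeric(x$data)
  if (inherits(x, "thala_cbt") && !is.null(x$weight_data) &&
      !isFALSE(weighted)) {
    vals <- as.numeric(x$weight_data)
    weighted <- TRUE
  }
  pos <- vals > 0
  if (!any(pos)) stop("empty volume: centre of gravity undefined")
  if (is.null(weighted)) weighted <- any(vals != 0 & vals != 1)
  idx <- which(array(pos, dim(x$data)), arr.ind = TRUE)
  w <- if (weighted) vals[pos] else rep(1, nrow(idx))
  xyz <- voxel_to_world(x, idx)
  colSums(xyz * w) / sum(w)
}

#' Euclidean distance between centres of gravity
#'
#' The CBT side uses the intensity-weighted centroid of its suprathreshold
#' voxels; the atlas side the unweighted centroid of the mask. Both in
#' world mm.
#'
#' @param x CBT or weighted map (`thala_volume`).
#' @param y atlas mask (`thala_volume`), same affine.
#' @param weighted_x intensity-weight the first volume (default auto).
#' @return distance in mm.
#' @export
cog_distance <- function(x, y, weighted_x = NULL) {
  if (!same_grid(x, y)) stop("grid mismatch between the two volumes")
  cx <- center_of_gravity(x, weighted = weighted_x)
  cy <- center_of_gravity(y, weighted = FALSE)
  sqrt(sum((cx - cy)^2))
}

#' Sweep CBT metrics across a percentile grid
#'
#' Thresholds the map at every percentile of the grid and records Dice
#' overlap and centre-of-gravity distance against the atlas target, plus
#' the volumes involved. Degenerate thresholds (empty CBT) are flagged
#' missing rather than dropped.
#'
#' @param map probability map (`thala_volume` or `thala_cmap`).
#' @param atlas_target binary `thala_volume`.
#' @param grid integer percentiles within `[50, 100]` (default `50:100`).
#' @param intent optional intent label carried into the output.
#' @return tibble of class `thala_sweep`: `intent`, `percentile`, `dice`,
#'   `cog_mm`, `vol_x`, `vol_y`, `degenerate`.
#' @export
sweep_thresholds <- function(map, atlas_target, grid = 50:100,
                             intent = NA_character_) {
  if (inherits(map, "thala_cmap")) map <- cmap_volume(map)
  stopifnot(all(grid >= 50), all(grid <= 100), !is.unsorted(grid))
  vol_y <- sum(as_binary_array(atlas_target))
  rows <- purrr::map(grid, function(p) {
    cbt <- percentile_threshold(map, p, intent = intent)
    if (cbt$n_voxels == 0) {
      return(tibble::tibble(intent = intent, percentile = p,
                            dice = NA_real_, cog_mm = NA_real_,
                            vol_x = 0L, vol_y = vol_y, degenerate = TRUE))
    }
    tibble::tibble(
      intent = intent, percentile = p,
      dice = dice(cbt, atlas_target),
      cog_mm = cog_distance(cbt, atlas_target),
      vol_x = cbt$n_voxels, vol_y = vol_y, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("thala_sweep", class(out))
  out
}
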