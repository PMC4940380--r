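#' Scalar volume on a regular grid
#'
#' A `thala_volume` is a 3D array bound to a voxel-to-world affine. Voxel
#' indices follow the 0-based convention in world mapping: the world
#' coordinate (mm, RAS order) of the voxel stored at R index `(i, j, k)` is
#' `affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param data numeric, integer or logical 3D array.
#' @param affine 4x4 voxel-to-world matrix (mm). Default: identity scaled by
#'   `voxel_size_mm`.
#' @param voxel_size_mm per-axis spacing used when `affine` is not given.
#' @return object of class `thala_volume`.
#' @export
volume <- function(data, affine = NULL, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, affine = affine), class = "thala_volume")
}

#' @export
print.thala_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<thala_volume> %d x %d x %d, voxel %s mm\n",
              d[1], d[2], d[3],
              paste(signif(voxel_size(x), 3), collapse = " x ")))
  invisible(x)
}

#' @export
dim.thala_volume <- function(x) dim(x$data)

#' Per-axis voxel size in mm
#' @param vol a `thala_volume`.
#' @return numeric length-3 vector.
#' @export
voxel_size <- function(vol) {
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' Map voxel indices to world coordinates
#'
#' @param vol a `thala_volume`.
#' @param idx integer matrix (n x 3) of 1-based array indices, or a length-3
#'   vector.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  h <- cbind(idx - 1, 1)
  out <- h %*% t(vol$affine)
  out[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional, 1-based) voxel indices
#' @param vol a `thala_volume`.
#' @param xyz n x 3 matrix of world mm points, or a length-3 vector.
#' @return n x 3 matrix of fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE] + 1
}

#' World z-coordinate of every voxel (vectorized over the grid)
#' @noRd
voxel_world_z <- function(vol) {
  d <- dim(vol$data)
  ii <- rep(seq_len(d[1]) - 1L, times = d[2] * d[3])
  jj <- rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3])
  kk <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  a <- vol$affine
  array(a[3, 1] * ii + a[3, 2] * jj + a[3, 3] * kk + a[3, 4], dim = d)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry the affine.
#' @param vol a `thala_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `thala_volume`; `write_volume()` the path,
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data * 1)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume(array(as.numeric(img), dim = dim(img)),
         affine = unclass(RNifti::xform(img)))
}

#' Labelled anatomical volume
#'
#' Integer region labels plus a legend mapping region names to label ids and
#' the world z-coordinate of the AC-PC plane.
#'
#' @param data integer 3D array of non-negative labels (0 = background).
#' @param affine 4x4 voxel-to-world matrix.
#' @param legend named integer vector, region name -> label id.
#' @param acpc_z_mm world z of the AC-PC plane.
#' @return object of class `thala_labels` (inherits `thala_volume`).
#' @export
label_volume <- function(data, affine, legend, acpc_z_mm = NA_real_) {
  stopifnot(all(data >= 0), !is.null(names(legend)))
  v <- volume(data, affine = affine)
  v$legend <- legend
  v$acpc_z_mm <- acpc_z_mm
  class(v) <- c("thala_labels", class(v))
  v
}

#' Extract a named region as a binary mask
#'
#' Composite names (for instance a whole thalamus that contains separately
#' labelled nuclei) are resolved through the volume's `compose` table when
#' present; the union of the member regions is returned.
#'
#' @param labels a `thala_labels`.
#' @param name region name present in the legend or the composite table (a
#'   vector of names returns their union).
#' @return logical-valued `thala_volume`.
#' @export
label_mask <- function(labels, name) {
  name <- resolve_region_names(labels, name)
  bad <- setdiff(name, names(labels$legend))
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  ids <- labels$legend[name]
  volume(array(labels$data %in% ids, dim = dim(labels$data)),
         affine = labels$affine)
}

#' @export
print.thala_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<thala_labels> %d x %d x %d, %d regions, AC-PC z = %s mm\n",
              d[1], d[2], d[3], length(x$legend), format(x$acpc_z_mm)))
  invisible(x)
}
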