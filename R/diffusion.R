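#' Fit diffusion tensors by log-linear least squares
#'
#' Per-voxel symmetric tensor fit of the monoexponential model
#' `S = S0 exp(-b g' D g)`. Voxels with any non-positive signal are masked
#' out and their count reported.
#'
#' @param dwi a `thala_dwi` stack (see [simulate_dwi()]), i.e. a list with
#'   `data` (4D array), `bvals`, `bvecs`, `affine`.
#' @param mask optional logical 3D array restricting the fit.
#' @return object of class `thala_tensor`: `d6` (n_voxels x 6 matrix,
#'   `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`), `evals` (n_voxels x 3, sorted
#'   descending), `evecs` (3 x 3 x n_voxels, columns matching `evals`),
#'   `mask`, `dims`, `affine`, `log_s0`.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "thala_dwi"))
  n <- dim(dwi$data)[1:3]
  nvol <- dim(dwi$data)[4]
  b <- dwi$bvals
  g <- dwi$bvecs
  if (sum(b == 0) < 1) stop("need at least one unweighted (b=0) volume")
  q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  X <- cbind(1, -b * q)
  if (qr(X)$rank < 7)
    stop("tensor fit infeasible: need >= 6 non-collinear weighted directions")
  if (is.null(mask)) mask <- array(TRUE, n)
  sig <- matrix(dwi$data, prod(n), nvol)
  pos <- rowSums(sig <= 0) == 0
  dropped <- sum(mask & !array(pos, n))
  if (dropped > 0)
    message(dropped, " voxel(s) with non-positive signal masked out")
  fit_mask <- as.vector(mask) & pos
  coef <- matrix(NA_real_, prod(n), 7)
  if (any(fit_mask)) {
    beta <- t(qr.solve(X, t(log(sig[fit_mask, , drop = FALSE]))))
    coef[fit_mask, ] <- beta
  }
  evals <- matrix(NA_real_, prod(n), 3)
  evecs <- array(NA_real_, c(3, 3, prod(n)))
  for (v in which(fit_mask)) {
    D <- matrix(c(coef[v, 2], coef[v, 5], coef[v, 6],
                  coef[v, 5], coef[v, 3], coef[v, 7],
                  coef[v, 6], coef[v, 7], coef[v, 4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)  # eigen() returns decreasing order
    evals[v, ] <- e$values
    evecs[, , v] <- e$vectors
  }
  structure(list(d6 = coef[, c(2, 3, 4, 5, 6, 7), drop = FALSE],
                 log_s0 = coef[, 1],
                 evals = evals, evecs = evecs,
                 mask = array(fit_mask, n), dims = n, affine = dwi$affine),
            class = "thala_tensor")
}

#' Fractional anisotropy of a tensor field
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, clipped to
#' `[0, 1]`. Zero-trace voxels get FA 0 and are counted.
#'
#' @param tensors a `thala_tensor` (or a numeric matrix / length-3 vector of
#'   eigenvalues, for direct evaluation).
#' @return a `thala_volume` of FA values (or a numeric vector for raw
#'   eigenvalue input).
#' @export
compute_fa <- function(tensors) {
  if (is.numeric(tensors)) {
    ev <- if (is.matrix(tensors)) tensors else matrix(tensors, nrow = 1)
    return(fa_from_evals(ev))
  }
  stopifnot(inherits(tensors, "thala_tensor"))
  fa <- fa_from_evals(tensors$evals)
  fa[is.na(fa)] <- 0
  volume(array(fa, tensors$dims), affine = tensors$affine)
}

fa_from_evals <- function(ev) {
  mn <- rowMeans(ev)
  num <- sqrt(rowSums((ev - mn)^2))
  den <- sqrt(rowSums(ev^2))
  zero <- !is.na(den) & den == 0
  n_zero <- sum(zero)
  if (n_zero > 0) message(n_zero, " zero-trace voxel(s): FA set to 0")
  fa <- sqrt(1.5) * num / den
  fa[zero] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Derive a Watson orientation field from a fitted tensor field
#'
#' The concentration is taken proportional to the tensor linearity,
#' `kappa = c * (lambda1 - lambda2) / lambda1` (floored at a small positive
#' value), a parametric stand-in for a posterior orientation distribution.
#'
#' @param tensors a `thala_tensor`.
#' @param kappa_scale the proportionality constant `c` (default 50).
#' @param kappa_floor minimum concentration on valid voxels.
#' @return a `thala_orientation`.
#' @export
orientation_from_tensor <- function(tensors, kappa_scale = 50,
                                    kappa_floor = 0.5) {
  n <- tensors$dims
  nv <- prod(n)
  dir1 <- array(0, c(n, 3L)); dir1[, , , 3] <- 1
  kap <- array(kappa_floor, n)
  idx <- which(tensors$mask)
  v1 <- t(tensors$evecs[, 1, idx])
  flat <- matrix(dir1, nv, 3)
  flat[idx, ] <- v1
  l1 <- tensors$evals[idx, 1]
  l2 <- tensors$evals[idx, 2]
  lin <- ifelse(l1 > 0, (l1 - l2) / l1, 0)
  kap[idx] <- pmax(kappa_scale * lin, kappa_floor)
  orientation_field(array(flat, c(n, 3L)), kap, tensors$affine,
                    mask = tensors$mask)
}

#' Draw unit vectors from a Watson distribution
#'
#' Axial (antipodally symmetric) Watson distribution with density
#' proportional to `exp(kappa * (mu . x)^2)` on the sphere, sampled with a
#' deterministic counter-based RNG stream.
#'
#' @param n number of draws.
#' @param mu mean axis (unit length).
#' @param kappa concentration (> 0; `Inf` returns `mu` with random sign).
#' @param seed integer stream seed.
#' @return n x 3 matrix of unit vectors.
#' @export
rwatson <- function(n, mu, kappa, seed = 1L) {
  mu <- mu / sqrt(sum(mu^2))
  rwatson_cpp(as.integer(n), as.numeric(mu), as.numeric(kappa),
              as.integer(seed))
}

#' Expected angular deviation of a Watson distribution
#'
#' Numerically integrates `E[acos(|t|)]` for `t = mu . x` under the axial
#' Watson density, for comparison with Monte-Carlo draws.
#'
#' @param kappa concentration.
#' @return expected angle to the mean axis, in radians.
#' @export
watson_expected_angle <- function(kappa) {
  f <- function(t) exp(kappa * t^2)
  z <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  num <- stats::integrate(function(t) acos(t) * f(t), 0, 1,
                          rel.tol = 1e-10)$value
  num / z
}

#' Sample one propagation direction from an orientation field
#'
#' Chooses a fiber population proportionally to its volume fraction, draws
#' from the Watson distribution about its mean, and flips the sign so the
#' draw has non-negative dot product with the previous direction (pass the
#' zero vector to keep the stored orientation sign).
#'
#' @param field a `thala_orientation`.
#' @param voxel 1-based voxel index triple.
#' @param previous_direction unit vector (or `c(0,0,0)` on the first step).
#' @param seed integer stream seed.
#' @param counter draw counter within the stream.
#' @return unit vector, or `NULL` if the voxel is outside the valid mask.
#' @export
sample_orientation <- function(field, voxel, previous_direction = c(0, 0, 0),
                               seed = 1L, counter = 0L) {
  v <- as.integer(voxel)
  n <- dim(field$kappa)
  if (any(v < 1) || any(v > n) || !field$mask[v[1], v[2], v[3]])
    return(NULL)
  sample_orientation_cpp(
    field$dir1, field$dir2, field$frac1, field$kappa, dim(field$kappa),
    v - 1L, as.numeric(previous_direction), as.integer(seed),
    as.integer(counter))
}
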