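# Fixtures are generated in code; nothing is read from disk.

# constant-direction orientation field
uniform_field <- function(n = c(16L, 16L, 16L), dir = c(0, 0, 1),
                          kappa = Inf, voxel_mm = c(1, 1, 1),
                          mask = NULL) {
  dir <- dir / sqrt(sum(dir^2))
  dir1 <- array(0, c(n, 3))
  for (a in 1:3) dir1[, , , a] <- dir[a]
  orientation_field(dir1, array(kappa, n), diag(c(voxel_mm, 1)),
                    mask = mask)
}

# tangent field of concentric circles about centre C in the x-y plane,
# restricted to polar angles <= max_angle_deg (so a streamline launched at
# angle 0 traverses a known arc and exits); 1 mm voxels
arc_field <- function(n = c(48L, 48L, 48L), C = c(24, 24),
                      max_angle_deg = 60, kappa = Inf) {
  xs <- seq_len(n[1]) - 1
  ys <- seq_len(n[2]) - 1
  dx <- outer(xs - C[1], rep(1, n[2]))
  dy <- outer(rep(1, n[1]), ys - C[2])
  r <- sqrt(dx^2 + dy^2)
  r[r < 1e-9] <- 1
  tx <- -dy / r
  ty <- dx / r
  ang <- atan2(dy, dx) * 180 / pi
  dir1 <- array(0, c(n, 3))
  msk <- array(FALSE, n)
  for (k in seq_len(n[3])) {
    dir1[, , k, 1] <- tx
    dir1[, , k, 2] <- ty
    msk[, , k] <- ang <= max_angle_deg
  }
  orientation_field(dir1, array(kappa, n), diag(c(1, 1, 1, 1)), mask = msk)
}

# circular-tangent field with a small inward radial component: the slight
# contraction cancels the outward Euler drift, so a streamline closes onto
# its own trail and must terminate by the loop rule
spiral_field <- function(n = c(48L, 48L, 48L), C = c(24, 24),
                         beta = 0.025) {
  xs <- seq_len(n[1]) - 1
  ys <- seq_len(n[2]) - 1
  dx <- outer(xs - C[1], rep(1, n[2]))
  dy <- outer(rep(1, n[1]), ys - C[2])
  r <- sqrt(dx^2 + dy^2)
  r[r < 1e-9] <- 1
  vx <- -dy / r - beta * dx / r
  vy <- dx / r - beta * dy / r
  nrm <- sqrt(vx^2 + vy^2)
  vx <- vx / nrm; vy <- vy / nrm
  dir1 <- array(0, c(n, 3))
  for (k in seq_len(n[3])) {
    dir1[, , k, 1] <- vx
    dir1[, , k, 2] <- vy
  }
  orientation_field(dir1, array(Inf, n), diag(c(1, 1, 1, 1)))
}

# binary mask of the angular sector [a1, a2] deg and radial band r_range
# around C, full z extent, on the arc_field grid
arc_sector_mask <- function(n, C, r_range, ang_range) {
  xs <- seq_len(n[1]) - 1
  ys <- seq_len(n[2]) - 1
  dx <- outer(xs - C[1], rep(1, n[2]))
  dy <- outer(rep(1, n[1]), ys - C[2])
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) * 180 / pi
  sl <- r >= r_range[1] & r <= r_range[2] &
    ang >= ang_range[1] & ang <= ang_range[2]
  arr <- array(FALSE, n)
  for (k in seq_len(n[3])) arr[, , k] <- sl
  volume(arr, affine = diag(c(1, 1, 1, 1)))
}

# random non-negative map with a controllable fraction of zeros
random_map <- function(n, seed, zero_frac = 0.5) {
  set.seed(seed)
  vals <- stats::runif(prod(n))
  vals[stats::runif(prod(n)) < zero_frac] <- 0
  volume(array(vals, n), affine = diag(c(1, 1, 1, 1)))
}

random_mask <- function(n, seed, p_on = 0.3) {
  set.seed(seed)
  volume(array(stats::runif(prod(n)) < p_on, n),
         affine = diag(c(1, 1, 1, 1)))
}

## ---- independent brute-force oracles --------------------------------------

dice_oracle <- function(a, b) {
  ia <- which(as_arr(a) != 0)
  ib <- which(as_arr(b) != 0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

as_arr <- function(x) if (inherits(x, "thala_volume")) x$data else x

# type-7 quantile written out from the order statistics: linear
# interpolation at index 1 + (n-1)p, exact at ties
quantile7_oracle <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  index <- (n - 1) * prob + 1
  lo <- floor(index)
  hi <- ceiling(index)
  qs <- x[lo]
  if (index > lo && x[hi] != qs) {
    h <- index - lo
    qs <- (1 - h) * qs + h * x[hi]
  }
  qs
}

# threshold a map at percentile p of positive values, >= rule, plain loops
cbt_oracle <- function(map, p) {
  arr <- as_arr(map)
  cutoff <- quantile7_oracle(arr[arr > 0], p / 100)
  arr >= cutoff
}

# centre of gravity by explicit per-voxel enumeration under the affine
cog_oracle <- function(vol, weighted) {
  arr <- as_arr(vol)
  n <- dim(arr)
  acc <- c(0, 0, 0)
  wsum <- 0
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    v <- arr[i, j, k]
    if (v > 0) {
      w <- if (weighted) v else 1
      p <- (vol$affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
      acc <- acc + w * p
      wsum <- wsum + w
    }
  }
  acc / wsum
}

# iterated 6-connected dilation == L1 ball of radius `iter` around each voxel
dilate_oracle <- function(mask, iter) {
  arr <- as_arr(mask) != 0
  n <- dim(arr)
  out <- array(FALSE, n)
  on <- which(arr, arr.ind = TRUE)
  for (r in seq_len(nrow(on))) {
    c0 <- on[r, ]
    for (di in -iter:iter) for (dj in -iter:iter) for (dk in -iter:iter) {
      if (abs(di) + abs(dj) + abs(dk) > iter) next
      p <- c0 + c(di, dj, dk)
      if (all(p >= 1) && all(p <= n)) out[p[1], p[2], p[3]] <- TRUE
    }
  }
  out
}

## ---- reproducibility-recovery replicate (tracking-based) ------------------

# one replicate of the scanner >> subject recovery experiment: a small
# 6-subject x 3-scanner phantom with a dominant per-scanner orientation
# tilt, tracked for the vlpv intent (left), CBTs at the 75th percentile
repro_recovery_replicate <- function(rep_seed,
                                     n_subjects = 6, n_scanners = 3,
                                     subject_displacement_mm = 0.25,
                                     scanner_dispersion_delta = c(30, 30, 30),
                                     tilt_base = 100,
                                     samples = 100) {
  cfg <- phantom_config(grid_shape = c(32, 36, 32),
                        n_subjects = n_subjects, n_scanners = n_scanners,
                        subject_displacement_mm = subject_displacement_mm,
                        scanner_dispersion_delta = scanner_dispersion_delta,
                        tilt_base = tilt_base,
                        master_seed = rep_seed)
  atlas <- generate_atlas(cfg)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj <- generate_subject(atlas, s, cfg)
    sp <- intent_spec(subj$labels, "vlpv", "l")
    for (sc in seq_len(n_scanners)) {
      f <- apply_scanner(subj$field, sc, cfg)
      cm <- track_seed_mask(f, sp$seed, sp$targets,
                            tracking_params(samples_per_seed_voxel = samples),
                            master_seed = 1000 * rep_seed + 10 * s + sc)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = s, scanner = sc,
        cbt = list(percentile_threshold(cmap_volume(cm), 75)))
    }
  }
  units <- dplyr::bind_rows(rows)
  glance(decompose_variability(pairwise_dice(units), cbt_units = units))
}
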