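#' Configuration for the synthetic diffusion phantom
#'
#' The phantom emulates a co-registered multi-subject, multi-scanner DTI
#' study: a mirror-symmetric "brain" with two thalami containing a
#' VLpv-like and a VPLp-like nucleus, cortical target slabs (precentral,
#' postcentral, supplementary motor), cerebellar structures (dentate,
#' superior cerebellar peduncle, red nucleus), thalamocortical fiber
#' bundles and a decussating cerebello-thalamic arc. Subjects differ by a
#' smooth random warp; scanners differ by added orientation dispersion, a
#' systematic per-voxel direction tilt and multiplicative signal noise.
#'
#' @param grid_shape voxel counts per axis (each >= 32).
#' @param voxel_size_mm per-axis spacing in mm.
#' @param n_subjects,n_scanners design size. Defaults mirror a four-subject,
#'   three-vendor study.
#' @param subject_displacement_mm RMS magnitude (mm) of the smooth
#'   inter-subject warp; 0 disables it.
#' @param scanner_dispersion_delta additive reduction of the orientation
#'   concentration kappa per scanner step beyond the first (scalar, or a
#'   vector of per-scanner reductions with the first usually 0).
#' @param scanner_noise_sd SD of multiplicative intensity noise per scanner
#'   step in simulated DWI signals.
#' @param master_seed integer seed; the whole phantom set is a pure function
#'   of the configuration.
#' @param acquisition list with `b_value` (s/mm^2, default 1000),
#'   `n_directions` (default 32), `s0`, and the tensor eigenvalues used for
#'   signal simulation (`lambda_parallel`, `lambda_perp`, `lambda_iso`,
#'   mm^2/s).
#' @param kappa_bundle,kappa_background Watson concentration inside fiber
#'   bundles and elsewhere.
#' @param bundle_radius_mm tube radius of the fiber bundles.
#' @param tilt_base scale constant for the scanner-specific systematic
#'   direction tilt: directions are perturbed by Gaussian noise of amplitude
#'   `sqrt(delta / tilt_base)`.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 54L, 48L),
                           voxel_size_mm = c(2, 2, 2),
                           n_subjects = 4L,
                           n_scanners = 3L,
                           subject_displacement_mm = 2,
                           scanner_dispersion_delta = 20,
                           scanner_noise_sd = 0.02,
                           master_seed = 42L,
                           acquisition = list(),
                           kappa_bundle = 60,
                           kappa_background = 4,
                           bundle_radius_mm = 3.2,
                           tilt_base = 2000) {
  acq <- utils::modifyList(
    list(b_value = 1000, n_directions = 32L, s0 = 100,
         lambda_parallel = 1.7e-3, lambda_perp = 3e-4, lambda_iso = 8e-4),
    acquisition)
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_subjects = as.integer(n_subjects),
              n_scanners = as.integer(n_scanners),
              subject_displacement_mm = subject_displacement_mm,
              scanner_dispersion_delta = scanner_dispersion_delta,
              scanner_noise_sd = scanner_noise_sd,
              master_seed = as.integer(master_seed),
              acquisition = acq,
              kappa_bundle = kappa_bundle,
              kappa_background = kappa_background,
              bundle_radius_mm = bundle_radius_mm,
              tilt_base = tilt_base)
  stopifnot(length(cfg$grid_shape) == 3L, length(cfg$voxel_size_mm) == 3L)
  if (any(cfg$grid_shape < 32L))
    stop("grid_shape must be at least 32 voxels along every axis")
  stopifnot(cfg$n_subjects >= 1L, cfg$n_scanners >= 1L,
            cfg$subject_displacement_mm >= 0,
            all(cfg$scanner_dispersion_delta >= 0),
            all(cfg$scanner_noise_sd >= 0),
            cfg$acquisition$n_directions >= 6L)
  class(cfg) <- "phantom_config"
  cfg
}

# per-scanner kappa reduction: a scalar is a per-step increment beyond the
# reference scanner 1; a vector gives explicit per-scanner reductions
scanner_delta <- function(config, scanner_index) {
  d <- config$scanner_dispersion_delta
  if (length(d) >= 2) {
    if (scanner_index > length(d))
      stop("scanner_dispersion_delta vector shorter than n_scanners")
    d[scanner_index]
  } else {
    d * (scanner_index - 1)
  }
}

# deterministic hierarchical sub-seed from integer components (minstd chain,
# all arithmetic exact in doubles)
derive_seed <- function(...) {
  s <- 1
  for (v in c(...)) {
    s <- (48271 * ((s + abs(v) + 1) %% 2147483647)) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

## ---- geometry -------------------------------------------------------------
## Region centres and semi-axes are defined as fractions of a reference
## 48 x 54 x 48 grid and rescaled to the configured grid, so any grid
## >= 32^3 carries the same topology. x: left -> right, y: posterior ->
## anterior, z: inferior -> superior. The midline is at x fraction 0.5.

.ref <- c(47, 53, 47)
.fr <- function(v) v / .ref
.mirror <- function(f) c(1 - f[1], f[2], f[3])

phantom_geometry <- function() {
  ell <- function(name, id, center, semi) {
    list(name = name, id = id, kind = "ellipsoid",
         center = .fr(center), semi = semi / .ref)
  }
  box <- function(name, id, lo, hi) {
    list(name = name, id = id, kind = "box", lo = .fr(lo), hi = .fr(hi))
  }
  mir <- function(r, name, id) {
    r$name <- name; r$id <- id
    if (r$kind == "ellipsoid") {
      r$center <- .mirror(r$center)
    } else {
      x <- sort(c(1 - r$lo[1], 1 - r$hi[1]))
      r$lo[1] <- x[1]; r$hi[1] <- x[2]
    }
    r
  }
  thal_l <- ell("thalamus_shell_l", 1L, c(15.5, 28, 26), c(4.5, 6.5, 4))
  vlpv_l <- ell("vlpv_l", 2L, c(17, 31, 26), c(2.4, 2.8, 2.4))
  vplp_l <- ell("vplp_l", 3L, c(17, 25, 26), c(2.4, 2.6, 2.4))
  prec_l <- box("precentral_l", 7L, c(10, 29, 41), c(21, 33, 45))
  postc_l <- box("postcentral_l", 8L, c(10, 22, 41), c(21, 26, 45))
  sma_l <- box("sma_l", 9L, c(10, 36, 41), c(21, 40, 45))
  cb_l <- ell("cerebellum_l", 13L, c(16, 13, 8), c(7, 6, 5.5))
  dent_l <- ell("dentate_l", 15L, c(16, 13, 8), c(2, 2, 2))
  scp_l <- ell("scp_l", 17L, c(19.5, 18, 14), c(1.8, 2.2, 2.5))
  rn_l <- ell("red_nucleus_l", 19L, c(20.5, 26, 19), c(1.6, 1.8, 1.8))
  regions <- list(
    thal_l, mir(thal_l, "thalamus_shell_r", 4L),
    vlpv_l, mir(vlpv_l, "vlpv_r", 5L),
    vplp_l, mir(vplp_l, "vplp_r", 6L),
    prec_l, mir(prec_l, "precentral_r", 10L),
    postc_l, mir(postc_l, "postcentral_r", 11L),
    sma_l, mir(sma_l, "sma_r", 12L),
    cb_l, mir(cb_l, "cerebellum_r", 14L),
    dent_l, mir(dent_l, "dentate_r", 16L),
    scp_l, mir(scp_l, "scp_r", 18L),
    rn_l, mir(rn_l, "red_nucleus_r", 20L))
  ## painting order: nuclei and deep structures override the larger shells
  order <- c("thalamus_shell_l", "thalamus_shell_r",
             "cerebellum_l", "cerebellum_r",
             "precentral_l", "precentral_r", "postcentral_l", "postcentral_r",
             "sma_l", "sma_r",
             "vlpv_l", "vlpv_r", "vplp_l", "vplp_r",
             "dentate_l", "dentate_r", "scp_l", "scp_r",
             "red_nucleus_l", "red_nucleus_r")
  names(regions) <- vapply(regions, `[[`, "", "name")
  list(regions = regions[order], acpc_z_frac = 25 / 47)
}

# bundle centreline control points in grid fractions; ctt_<side> feeds the
# <side> thalamus and is seeded from the contralateral dentate
phantom_centerline_specs <- function() {
  left <- list(
    vlpv_precentral_l  = rbind(c(17, 31, 25), c(16, 31, 33), c(15.5, 31, 44)),
    vlpv_sma_l         = rbind(c(17, 31, 25), c(15, 35, 34), c(14, 38, 44)),
    vplp_postcentral_l = rbind(c(17, 25, 25), c(16, 24, 34), c(15.5, 24, 44)),
    ctt_l = rbind(c(31, 13, 8), c(27.5, 18, 14), c(23.5, 22, 17),
                  c(20.5, 26, 19), c(17.5, 30, 24)))
  right <- lapply(left, function(m) {
    m[, 1] <- .ref[1] - m[, 1]
    m
  })
  names(right) <- sub("_l$", "_r", names(left))
  out <- c(left, right)
  lapply(out, function(m) sweep(m, 2, .ref, "/"))
}

composite_regions <- function() {
  list(
    thalamus_l = c("thalamus_shell_l", "vlpv_l", "vplp_l"),
    thalamus_r = c("thalamus_shell_r", "vlpv_r", "vplp_r"),
    thalamus = c("thalamus_shell_l", "vlpv_l", "vplp_l",
                 "thalamus_shell_r", "vlpv_r", "vplp_r"),
    vlpv = c("vlpv_l", "vlpv_r"),
    vplp = c("vplp_l", "vplp_r"),
    precentral = c("precentral_l", "precentral_r"),
    postcentral = c("postcentral_l", "postcentral_r"),
    sma = c("sma_l", "sma_r"),
    cerebellum = c("cerebellum_l", "cerebellum_r", "dentate_l", "dentate_r"),
    cerebellum_l_full = c("cerebellum_l", "dentate_l"),
    cerebellum_r_full = c("cerebellum_r", "dentate_r"))
}

# Voxel indices of one region. Ellipsoids keep by metric <= 1; when
# `fixed_count` is given the that-many smallest-metric voxels are taken
# instead, so a displaced region keeps exactly its reference volume. Boxes
# are shifted by whole voxels (`shift_vox`), which also conserves volume.
region_voxels <- function(region, dims, fixed_count = NULL,
                          shift_vox = c(0L, 0L, 0L)) {
  n <- dims
  if (region$kind == "ellipsoid") {
    cvox <- region$center * (n - 1) + 1
    svox <- pmax(region$semi * (n - 1), 1e-9)
    pad <- if (is.null(fixed_count)) 0 else 1
    lo <- pmax(floor(cvox - svox - pad), 1)
    hi <- pmin(ceiling(cvox + svox + pad), n)
    if (any(lo > hi)) return(NULL)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- ((ii - cvox[1]) / svox[1])^2
    dy2 <- ((jj - cvox[2]) / svox[2])^2
    dz2 <- ((kk - cvox[3]) / svox[3])^2
    m <- outer(outer(dx2, dy2, "+"), dz2, "+")
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    if (is.null(fixed_count)) {
      idx[as.vector(m) <= 1, , drop = FALSE]
    } else {
      keep <- order(as.vector(m))[seq_len(min(fixed_count, nrow(idx)))]
      idx[keep, , drop = FALSE]
    }
  } else {
    lo <- pmax(round(region$lo * (n - 1)) + 1 + shift_vox, 1)
    hi <- pmin(round(region$hi * (n - 1)) + 1 + shift_vox, n)
    if (any(lo > hi)) return(NULL)
    as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                          k = lo[3]:hi[3]))
  }
}

paint_region <- function(arr, region, dims, fixed_count = NULL,
                         shift_vox = c(0L, 0L, 0L)) {
  idx <- region_voxels(region, dims, fixed_count, shift_vox)
  if (!is.null(idx) && nrow(idx) > 0) arr[idx] <- region$id
  arr
}

#' Generate the ground-truth phantom atlas
#'
#' Builds the common-space label volume (all regions, mirror-symmetric) and
#' the analytic bundle centerlines used to realize the orientation fields.
#'
#' @param config a [phantom_config()].
#' @return a `thala_labels` volume with, additionally, `$centerlines` (named
#'   list of control-point matrices in world mm) and `$compose` (composite
#'   region definitions understood by [label_mask()]).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$grid_shape
  affine <- diag(c(config$voxel_size_mm, 1))
  geo <- phantom_geometry()
  arr <- array(0L, dim = n)
  for (r in geo$regions) arr <- paint_region(arr, r, n)
  legend <- vapply(geo$regions, `[[`, integer(1), "id")
  missing <- names(legend)[!legend %in% arr]
  if (length(missing))
    stop("grid too small to place region(s): ", paste(missing, collapse = ", "))
  acpc_z <- geo$acpc_z_frac * (n[3] - 1) * config$voxel_size_mm[3]
  lab <- label_volume(arr, affine, legend, acpc_z_mm = acpc_z)
  lab$compose <- composite_regions()
  lab$region_counts <- vapply(geo$regions, function(r) {
    idx <- region_voxels(r, n)
    if (is.null(idx)) 0L else nrow(idx)
  }, integer(1))
  cl <- lapply(phantom_centerline_specs(), function(m) {
    vox0 <- sweep(m, 2, n - 1, "*")  # 0-based voxel coords
    sweep(vox0, 2, config$voxel_size_mm, "*")
  })
  lab$centerlines <- cl
  lab
}

#' Densify a centerline by cubic-spline interpolation over arc length
#'
#' @param ctrl matrix of control points (world mm, ordered).
#' @param step_mm spacing of the returned polyline.
#' @return matrix of points (world mm) tracing the curve.
#' @export
densify_centerline <- function(ctrl, step_mm = 0.5) {
  d <- sqrt(rowSums(diff(ctrl)^2))
  s <- c(0, cumsum(d))
  n_out <- max(ceiling(s[length(s)] / step_mm) + 1, 2)
  ss <- seq(0, s[length(s)], length.out = n_out)
  out <- vapply(1:3, function(a) {
    stats::spline(s, ctrl[, a], xout = ss, method = "natural")$y
  }, numeric(n_out))
  out
}

# resolve composite names before falling back to atomic legend names
resolve_region_names <- function(labels, name) {
  comp <- labels$compose
  out <- character(0)
  for (nm in name) {
    if (!is.null(comp) && nm %in% names(comp)) out <- c(out, comp[[nm]])
    else out <- c(out, nm)
  }
  unique(out)
}

#' Orientation field constructor
#'
#' Per-voxel Watson orientation model: up to two fiber populations with mean
#' directions `dir1`/`dir2`, volume fraction `frac1` for the first, and a
#' shared concentration `kappa` (use `Inf` for a deterministic field).
#'
#' @param dir1 4D array (nx, ny, nz, 3) of unit mean directions.
#' @param kappa 3D array of Watson concentrations (> 0 on valid voxels).
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask logical 3D array of valid voxels.
#' @param dir2 optional second-population directions (zero rows = absent).
#' @param frac1 3D array of first-population volume fractions in (0, 1].
#' @return object of class `thala_orientation`.
#' @export
orientation_field <- function(dir1, kappa, affine, mask = NULL,
                              dir2 = NULL, frac1 = NULL) {
  d <- dim(dir1)
  stopifnot(length(d) == 4L, d[4] == 3L)
  grid <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (is.null(frac1)) frac1 <- array(1, grid)
  if (is.null(dir2)) dir2 <- array(0, c(grid, 3L))
  stopifnot(identical(dim(kappa), grid), identical(dim(mask), grid))
  structure(list(dir1 = dir1, dir2 = dir2, frac1 = frac1, kappa = kappa,
                 mask = mask, affine = affine, subject_index = NA_integer_),
            class = "thala_orientation")
}

#' @export
print.thala_orientation <- function(x, ...) {
  d <- dim(x$kappa)
  cat(sprintf(
    "<thala_orientation> %d x %d x %d, %d valid voxels, kappa %s-%s\n",
    d[1], d[2], d[3], sum(x$mask),
    format(min(x$kappa[x$mask]), digits = 3),
    format(max(x$kappa[x$mask]), digits = 3)))
  invisible(x)
}

# realize bundles as tubes around the (possibly warped) centerlines
build_orientation_field <- function(labels, centerlines, config) {
  n <- dim(labels$data)
  vs <- config$voxel_size_mm
  dir1 <- array(0, c(n, 3L)); dir1[, , , 3] <- 1
  dir2 <- array(0, c(n, 3L))
  frac1 <- array(1, n)
  kappa <- array(config$kappa_background, n)
  bundle_of <- array(0L, n)
  rad_vox <- config$bundle_radius_mm / vs
  bid <- 0L
  for (nm in names(centerlines)) {
    bid <- bid + 1L
    pts <- densify_centerline(centerlines[[nm]], step_mm = 0.4 * min(vs))
    tang <- rbind(pts[2, ] - pts[1, ], diff(pts))
    tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
    for (p in seq_len(nrow(pts))) {
      cvox <- pts[p, ] / vs + 1  # 1-based fractional voxel
      lo <- pmax(floor(cvox - rad_vox), 1)
      hi <- pmin(ceiling(cvox + rad_vox), n)
      if (any(lo > hi)) next
      for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
        dmm <- ((i - cvox[1]) * vs[1])^2 + ((j - cvox[2]) * vs[2])^2 +
          ((k - cvox[3]) * vs[3])^2
        if (dmm > config$bundle_radius_mm^2) next
        cur <- bundle_of[i, j, k]
        if (cur == 0L || cur == bid) {
          bundle_of[i, j, k] <- bid
          dir1[i, j, k, ] <- tang[p, ]
          kappa[i, j, k] <- config$kappa_bundle
        } else if (all(dir2[i, j, k, ] == 0)) {
          # crossing of two distinct bundles: second population if the
          # directions genuinely differ
          if (abs(sum(dir1[i, j, k, ] * tang[p, ])) < 0.9) {
            dir2[i, j, k, ] <- tang[p, ]
            frac1[i, j, k] <- 0.5
          }
        }
      }
    }
  }
  orientation_field(dir1, kappa, labels$affine,
                    mask = array(TRUE, n), dir2 = dir2, frac1 = frac1)
}

# Smooth sinusoidal displacement field (mm), one array per axis. Each of
# the three low-frequency modes is a transverse plane wave (amplitude
# perpendicular to the physical wave vector), so the field is
# divergence-free in the continuum and the warp near-volume-preserving;
# phases and amplitude orientations are subject-specific.
subject_warp_field <- function(config, subject_index) {
  n <- config$grid_shape
  vs <- config$voxel_size_mm
  target <- config$subject_displacement_mm
  if (target == 0) return(NULL)
  set.seed(derive_seed(config$master_seed, 101L, subject_index))
  waves <- rbind(c(1, 0.5, 0), c(0, 1, 0.5), c(0.5, 0, 1))  # cycles per grid
  phases <- stats::runif(3, 0, 2 * pi)
  amps <- vapply(1:3, function(m) {
    k_phys <- 2 * pi * waves[m, ] / (n * vs)
    a <- stats::rnorm(3)
    a <- a - sum(a * k_phys) / sum(k_phys^2) * k_phys  # transverse
    a / sqrt(sum(a^2))
  }, numeric(3))  # 3 x 3, column = mode
  xs <- (seq_len(n[1]) - 1) / n[1]
  ys <- (seq_len(n[2]) - 1) / n[2]
  zs <- (seq_len(n[3]) - 1) / n[3]
  d <- list(array(0, n), array(0, n), array(0, n))
  for (m in 1:3) {
    w <- waves[m, ]
    arg <- 2 * pi * outer(outer(w[1] * xs, w[2] * ys, "+"), w[3] * zs, "+") +
      phases[m]
    s <- sin(arg)
    for (axis in 1:3) d[[axis]] <- d[[axis]] + amps[axis, m] * s
  }
  rms <- sqrt(mean(d[[1]]^2 + d[[2]]^2 + d[[3]]^2))
  lapply(d, function(a) a * target / rms)
}

# paint the displaced geometry for one subject: ellipsoid centres move by
# the local warp (constant voxel count), boxes shift by whole voxels
paint_displaced <- function(atlas, disp, config) {
  n <- config$grid_shape
  vs <- config$voxel_size_mm
  geo <- phantom_geometry()
  arr <- array(0L, n)
  for (r in geo$regions) {
    if (r$kind == "ellipsoid") {
      cw <- matrix(r$center * (n - 1) * vs, 1)
      d <- warp_at(disp, cw, config)[1, ]
      r$center <- r$center + d / ((n - 1) * vs)
      arr <- paint_region(arr, r, n,
                          fixed_count = atlas$region_counts[[r$name]])
    } else {
      cw <- matrix((r$lo + r$hi) / 2 * (n - 1) * vs, 1)
      d <- warp_at(disp, cw, config)[1, ]
      arr <- paint_region(arr, r, n, shift_vox = as.integer(round(d / vs)))
    }
  }
  arr
}

# displacement (mm) at world points, nearest-voxel lookup
warp_at <- function(disp, pts_mm, config) {
  n <- config$grid_shape
  vox <- round(sweep(pts_mm, 2, config$voxel_size_mm, "/")) + 1
  vox <- pmin(pmax(vox, 1), matrix(n, nrow(vox), 3, byrow = TRUE))
  cbind(disp[[1]][vox], disp[[2]][vox], disp[[3]][vox])
}

#' Generate one subject from the atlas
#'
#' Applies a smooth random warp (sum of three low-frequency, transverse
#' sinusoidal displacement fields with subject-specific random phases and
#' orientations, scaled to the configured RMS magnitude) to the atlas
#' anatomy and bundle centerlines, and realizes the subject's orientation
#' field. Region volumes are conserved: ellipsoidal regions are re-painted
#' at their displaced centres with their reference voxel counts, boxes
#' shift by whole voxels, and centerlines are displaced point by point.
#' With zero displacement the subject equals the atlas.
#'
#' @param atlas result of [generate_atlas()].
#' @param subject_index 1-based subject number (<= `n_subjects`).
#' @param config the [phantom_config()].
#' @return list with `labels` (`thala_labels`), `field`
#'   (`thala_orientation`), `centerlines` (warped, world mm) and `truth`
#'   (applied warp description).
#' @export
generate_subject <- function(atlas, subject_index, config) {
  stopifnot(subject_index >= 1, subject_index <= config$n_subjects)
  disp <- subject_warp_field(config, subject_index)
  scale_used <- 1
  if (is.null(disp)) {
    labels <- atlas
    cl <- atlas$centerlines
  } else {
    d <- disp
    for (try in 1:4) {
      arr <- paint_displaced(atlas, d, config)
      if (all(atlas$legend %in% arr)) break
      # warp pushed a region off-grid: clip by halving, keep a note
      scale_used <- scale_used / 2
      d <- lapply(d, function(a) a / 2)
      message("subject ", subject_index,
              ": warp clipped to RMS ", scale_used *
                config$subject_displacement_mm, " mm")
    }
    labels <- label_volume(arr, atlas$affine, atlas$legend,
                           acpc_z_mm = atlas$acpc_z_mm)
    labels$compose <- atlas$compose
    labels$region_counts <- atlas$region_counts
    cl <- lapply(atlas$centerlines, function(m) m + warp_at(d, m, config))
    disp <- d
  }
  labels$centerlines <- cl
  field <- build_orientation_field(labels, cl, config)
  field$subject_index <- as.integer(subject_index)
  list(labels = labels, field = field, centerlines = cl,
       truth = list(subject = subject_index, warp_scale = scale_used,
                    rms_mm = config$subject_displacement_mm * scale_used))
}

#' Apply a scanner effect to an orientation field
#'
#' Scanner `1` is the reference and leaves the field untouched. Later
#' scanners reduce the Watson concentration by `scanner_dispersion_delta`
#' per scanner step and additionally tilt every mean direction by a
#' systematic, scanner-specific random perturbation (a vendor bias drawn
#' from the scanner's own RNG stream, shared across subjects; repeating a
#' scanner reproduces the same field).
#'
#' @param field a `thala_orientation` (carrying its `subject_index`).
#' @param scanner_index 1-based scanner number.
#' @param config the [phantom_config()].
#' @return perturbed `thala_orientation`.
#' @export
apply_scanner <- function(field, scanner_index, config) {
  stopifnot(scanner_index >= 1, scanner_index <= config$n_scanners)
  delta <- scanner_delta(config, scanner_index)
  if (delta == 0) return(field)
  out <- field
  out$kappa <- pmax(field$kappa - delta, 0.5)
  eps <- sqrt(delta / config$tilt_base)
  # the tilt is a vendor bias: drawn from the scanner-specific stream, so it
  # is shared by every subject scanned on that scanner
  set.seed(derive_seed(config$master_seed, 202L, scanner_index))
  n <- dim(field$kappa)
  nv <- prod(n)
  perturb <- function(dirs) {
    flat <- matrix(dirs, nv, 3)
    live <- rowSums(flat^2) > 0
    flat[live, ] <- flat[live, ] +
      eps * matrix(stats::rnorm(3 * sum(live)), ncol = 3)
    nrm <- sqrt(rowSums(flat^2))
    flat[live, ] <- flat[live, ] / nrm[live]
    array(flat, c(n, 3L))
  }
  out$dir1 <- perturb(field$dir1)
  out$dir2 <- perturb(field$dir2)
  out$scanner_index <- as.integer(scanner_index)
  out
}

#' Evenly spread unit gradient directions (spherical Fibonacci scheme)
#' @param n number of directions (>= 6).
#' @return n x 3 matrix of unit vectors.
#' @export
gradient_directions <- function(n) {
  stopifnot(n >= 6)
  i <- seq_len(n) - 0.5
  z <- 1 - i / n          # upper hemisphere; diffusion is antipodal
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Monoexponential diffusion-weighted signal of a tensor field
#'
#' Stejskal-Tanner signal `S = S0 * exp(-b g' D g)` per voxel and gradient.
#'
#' @param d6 matrix (n_voxels x 6) of tensor components in the order
#'   `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz` (mm^2/s).
#' @param bvals vector of b-values (s/mm^2), one per volume.
#' @param bvecs matrix (n_volumes x 3) of unit gradient directions.
#' @param s0 unweighted signal.
#' @return matrix (n_voxels x n_volumes) of signals.
#' @export
dwi_signal <- function(d6, bvals, bvecs, s0 = 100) {
  g <- bvecs
  q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  s0 * exp(-(d6 %*% t(q)) %*% diag(bvals, length(bvals)))
}

#' Simulate a diffusion-weighted volume stack from an orientation field
#'
#' Builds a per-voxel tensor from the principal orientation (prolate tensor
#' inside bundles, isotropic elsewhere) and evaluates the monoexponential
#' signal for one b=0 volume plus `n_directions` weighted volumes, with
#' optional multiplicative Gaussian noise from the scanner-specific stream.
#'
#' @param field a `thala_orientation`.
#' @param config the [phantom_config()].
#' @param scanner_index scanner whose noise stream and `scanner_noise_sd`
#'   apply; `NULL` for noise-free data.
#' @return list of class `thala_dwi`: `data` (4D array), `bvals`, `bvecs`,
#'   `affine`.
#' @export
simulate_dwi <- function(field, config, scanner_index = NULL) {
  acq <- config$acquisition
  n <- dim(field$kappa)
  nv <- prod(n)
  dirs <- matrix(field$dir1, nv, 3)
  bundle <- as.vector(field$kappa >= 10)
  lp <- acq$lambda_parallel; lt <- acq$lambda_perp; li <- acq$lambda_iso
  d6 <- matrix(0, nv, 6)
  d6[, 1:3] <- li
  if (any(bundle)) {
    u <- dirs[bundle, , drop = FALSE]
    d6[bundle, 1] <- lt + (lp - lt) * u[, 1]^2
    d6[bundle, 2] <- lt + (lp - lt) * u[, 2]^2
    d6[bundle, 3] <- lt + (lp - lt) * u[, 3]^2
    d6[bundle, 4] <- (lp - lt) * u[, 1] * u[, 2]
    d6[bundle, 5] <- (lp - lt) * u[, 1] * u[, 3]
    d6[bundle, 6] <- (lp - lt) * u[, 2] * u[, 3]
  }
  bvecs <- rbind(c(0, 0, 0), gradient_directions(acq$n_directions))
  bvals <- c(0, rep(acq$b_value, acq$n_directions))
  sig <- dwi_signal(d6, bvals, bvecs, s0 = acq$s0)
  if (!is.null(scanner_index) && config$scanner_noise_sd > 0) {
    sub <- if (is.na(field$subject_index)) 0L else field$subject_index
    set.seed(derive_seed(config$master_seed, 303L, sub, scanner_index))
    sig <- sig * (1 + config$scanner_noise_sd *
                    matrix(stats::rnorm(length(sig)), nrow(sig)))
    sig <- pmax(sig, 1e-6)  # signals stay positive
  }
  structure(list(data = array(sig, c(n, length(bvals))),
                 bvals = bvals, bvecs = bvecs, affine = field$affine),
            class = "thala_dwi")
}

#' Generate a full multi-subject, multi-scanner phantom set
#'
#' Pure function of the configuration: atlas, per-subject warped instances,
#' and per-(subject, scanner) orientation fields.
#'
#' @param config a [phantom_config()].
#' @return list of class `thala_phantom_set` with `atlas`, `subjects` (list
#'   of [generate_subject()] results), `units` (tibble: subject, scanner,
#'   field list-column) and `config`.
#' @export
generate_phantom_set <- function(config) {
  atlas <- generate_atlas(config)
  subjects <- lapply(seq_len(config$n_subjects), function(s)
    generate_subject(atlas, s, config))
  units <- tidyr::expand_grid(subject = seq_len(config$n_subjects),
                              scanner = seq_len(config$n_scanners))
  units$field <- purrr::map2(units$subject, units$scanner, function(s, c)
    apply_scanner(subjects[[s]]$field, c, config))
  structure(list(atlas = atlas, subjects = subjects, units = units,
                 config = config),
            class = "thala_phantom_set")
}

#' @export
print.thala_phantom_set <- function(x, ...) {
  cat(sprintf("<thala_phantom_set> %d subject(s) x %d scanner(s), grid %s\n",
              x$config$n_subjects, x$config$n_scanners,
              paste(x$config$grid_shape, collapse = " x ")))
  invisible(x)
}

#' Write a phantom set to disk
#'
#' Volumes go out as NIfTI-1 (`.nii.gz`) sharing the common affine, the
#' label legend as a JSON sidecar, and the truth records (warp parameters,
#' scanner effects) as YAML.
#'
#' @param set a `thala_phantom_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(set$atlas, file.path(dir, "atlas_labels.nii.gz"))
  jsonlite::write_json(as.list(set$atlas$legend),
                       file.path(dir, "legend.json"), auto_unbox = TRUE)
  for (s in seq_along(set$subjects)) {
    write_volume(set$subjects[[s]]$labels,
                 file.path(dir, sprintf("sub-%02d_labels.nii.gz", s)))
  }
  truth <- list(
    config = unclass(set$config)[c("grid_shape", "voxel_size_mm",
                                   "n_subjects", "n_scanners",
                                   "subject_displacement_mm",
                                   "scanner_dispersion_delta",
                                   "scanner_noise_sd", "master_seed")],
    acpc_z_mm = set$atlas$acpc_z_mm,
    subjects = lapply(set$subjects, `[[`, "truth"))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
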