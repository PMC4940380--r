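#' Tracking parameters
#'
#' @param samples_per_seed_voxel streamlines launched per seed voxel
#'   (default 5000, the study protocol; scale down for quick runs).
#' @param step_mm propagation step; defaults to half the smallest voxel
#'   dimension at tracking time, and must not exceed the smallest voxel.
#' @param max_steps hard cap on steps per streamline.
#' @param curvature_limit_deg maximum per-step turn, in (0, 90].
#' @param seed_jitter jitter the start point uniformly within the seed
#'   voxel.
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(samples_per_seed_voxel = 5000L,
                            step_mm = NULL,
                            max_steps = 2000L,
                            curvature_limit_deg = 80,
                            seed_jitter = TRUE) {
  stopifnot(samples_per_seed_voxel >= 1,
            curvature_limit_deg > 0, curvature_limit_deg <= 90,
            max_steps >= 1)
  structure(list(samples_per_seed_voxel = as.integer(samples_per_seed_voxel),
                 step_mm = step_mm,
                 max_steps = as.integer(max_steps),
                 curvature_limit_deg = curvature_limit_deg,
                 seed_jitter = isTRUE(seed_jitter)),
            class = "tracking_params")
}

.termination_reasons <- c("target-hit", "mask-exit", "loop", "curvature",
                          "max-steps", "rejected", "target-miss")

resolve_step <- function(params, field) {
  vs <- sqrt(colSums(field$affine[1:3, 1:3]^2))
  step <- params$step_mm %||% (0.5 * min(vs))
  if (step <= 0 || step > min(vs) + 1e-9)
    stop("step_mm must be in (0, min voxel size]")
  step
}

`%||%` <- function(a, b) if (is.null(a)) b else a

field_args <- function(field) {
  list(dir1 = as.numeric(field$dir1), dir2 = as.numeric(field$dir2),
       frac1 = as.numeric(field$frac1), kappa = as.numeric(field$kappa),
       mask = as.logical(field$mask), dims = as.integer(dim(field$kappa)),
       ainv = solve(field$affine)[1:3, , drop = FALSE],
       afwd = field$affine[1:3, , drop = FALSE])
}

#' Propagate a single probabilistic streamline
#'
#' Iteratively samples a local orientation and advances by `step_mm`;
#' terminates on leaving the valid mask, exceeding the curvature limit,
#' revisiting an already-visited voxel (loops and recursions are not
#' allowed) or reaching `max_steps`.
#'
#' @param field a `thala_orientation`.
#' @param start_point world-mm start (must lie inside the valid mask).
#' @param params a [tracking_params()].
#' @param seed integer RNG stream seed.
#' @param sample_id index distinguishing streams from the same start.
#' @return object of class `thala_streamline`: `points` (n x 3 world mm) and
#'   `reason` (one of `"mask-exit"`, `"loop"`, `"curvature"`, `"max-steps"`).
#' @export
propagate <- function(field, start_point, params = tracking_params(),
                      seed = 1L, sample_id = 1L) {
  fa <- field_args(field)
  v0 <- round((solve(field$affine) %*% c(start_point, 1))[1:3])
  n <- dim(field$kappa)
  if (any(v0 < 0) || any(v0 > n - 1) ||
      !field$mask[v0[1] + 1, v0[2] + 1, v0[3] + 1])
    stop("rejected seed: start point outside the valid mask")
  res <- propagate_cpp(as.numeric(start_point), fa$dir1, fa$dir2, fa$frac1,
                       fa$kappa, fa$mask, fa$dims, fa$ainv, fa$afwd,
                       resolve_step(params, field),
                       cos(params$curvature_limit_deg * pi / 180),
                       params$max_steps, as.integer(seed),
                       as.integer(sample_id))
  structure(list(points = res$points,
                 reason = .termination_reasons[res$reason + 1]),
            class = "thala_streamline")
}

#' @export
print.thala_streamline <- function(x, ...) {
  cat(sprintf("<thala_streamline> %d points, terminated: %s\n",
              nrow(x$points), x$reason))
  invisible(x)
}

mask_indices <- function(mask) {
  which(array(as.logical(mask$data), dim(mask$data)), arr.ind = TRUE)
}

#' Seed-to-targets probabilistic tractography with back-projected counters
#'
#' Launches `samples_per_seed_voxel` streamlines from every voxel of the
#' seed mask. A sample is credited to the first target region it enters and
#' then terminated; per-seed-voxel counters form the back-projected
#' connectivity map, and the waytotal is the total number of samples that
#' reached any target.
#'
#' @param field a `thala_orientation`.
#' @param seed binary `thala_volume` (non-empty; e.g. the whole thalamus).
#' @param targets named list of binary `thala_volume` masks, disjoint from
#'   the seed.
#' @param params a [tracking_params()].
#' @param master_seed integer; identical inputs and seed reproduce the map
#'   exactly.
#' @return object of class `thala_cmap`: `seed_voxels` (n x 3, 1-based),
#'   `counts` (n_seeds x n_targets), `targets`, `waytotal`, `normalized`,
#'   `samples_per_voxel`, `reasons`, `dims`, `affine`.
#' @export
track_seed_mask <- function(field, seed, targets, params = tracking_params(),
                            master_seed = 1L) {
  stopifnot(inherits(field, "thala_orientation"))
  sv <- mask_indices(seed)
  if (nrow(sv) == 0) stop("empty seed mask")
  if (length(targets) == 0) stop("empty target set")
  if (is.null(names(targets)) || any(names(targets) == ""))
    stop("targets must be named")
  n <- dim(field$kappa)
  tl <- array(0L, n)
  for (t in seq_along(targets)) {
    m <- as.logical(targets[[t]]$data)
    tl[m & tl == 0L] <- t
  }
  if (any(tl[sv] != 0L)) stop("targets must be disjoint from the seed")
  fa <- field_args(field)
  res <- track_cpp(sv - 1L, fa$dir1, fa$dir2, fa$frac1, fa$kappa, fa$mask,
                   fa$dims, fa$ainv, fa$afwd,
                   as.integer(tl), length(targets),
                   integer(0), 0L, integer(0), 0L,
                   params$samples_per_seed_voxel, params$seed_jitter,
                   resolve_step(params, field),
                   cos(params$curvature_limit_deg * pi / 180),
                   params$max_steps, as.integer(master_seed),
                   FALSE, FALSE)
  stopifnot(res$waytotal == sum(res$counts))  # waytotal consistency
  structure(list(seed_voxels = sv, counts = res$counts,
                 targets = names(targets), waytotal = res$waytotal,
                 normalized = FALSE,
                 samples_per_voxel = params$samples_per_seed_voxel,
                 reasons = stats::setNames(as.integer(res$reasons),
                                           .termination_reasons),
                 dims = n, affine = field$affine),
            class = "thala_cmap")
}

#' @export
print.thala_cmap <- function(x, ...) {
  cat(sprintf(
    "<thala_cmap> %d seed voxels, targets [%s], waytotal %s%s\n",
    nrow(x$seed_voxels), paste(x$targets, collapse = ", "),
    format(x$waytotal), if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Render a connectivity map as a volume
#'
#' @param cmap a `thala_cmap`.
#' @param target a target name (default: sum over all targets).
#' @return `thala_volume` of per-seed-voxel connection values (zero outside
#'   the seed).
#' @export
cmap_volume <- function(cmap, target = NULL) {
  vals <- if (is.null(target)) rowSums(cmap$counts)
  else cmap$counts[, match(target, cmap$targets)]
  arr <- array(0, cmap$dims)
  arr[cmap$seed_voxels] <- vals
  volume(arr, affine = cmap$affine)
}

#' Normalize a connectivity map by its waytotal
#'
#' Divides every counter by the total number of samples that reached any
#' target. Downstream percentile thresholds are scale-free, so CBTs are
#' identical whether built from raw or normalized maps.
#'
#' @param cmap a `thala_cmap` (not already normalized).
#' @return normalized `thala_cmap`.
#' @export
normalize_by_waytotal <- function(cmap) {
  if (isTRUE(cmap$normalized)) stop("connectivity map already normalized")
  if (cmap$waytotal == 0) {
    warning("waytotal is 0: returning an all-zero normalized map")
    cmap$counts[] <- 0
  } else {
    cmap$counts <- cmap$counts / cmap$waytotal
  }
  cmap$normalized <- TRUE
  cmap
}

#' Ordered way-point specification
#'
#' @param waypoints ordered list of binary `thala_volume` masks that a
#'   streamline must traverse in sequence (gaps allowed, order inversions
#'   not).
#' @param target terminal target mask (`thala_volume`).
#' @return object of class `waypoint_spec`.
#' @export
waypoint_spec <- function(waypoints, target) {
  if (length(waypoints) == 0) stop("waypoint list must be non-empty")
  structure(list(waypoints = waypoints, target = target),
            class = "waypoint_spec")
}

#' Way-point filtered tractography (cerebello-thalamic tract)
#'
#' Streamlines seeded in `seed` are kept only if they enter the way-point
#' masks in the stated order (intervening non-waypoint voxels are allowed;
#' entering a later way-point before an earlier one rejects the sample) and
#' then reach the terminal target. Voxel-wise visitation counts of kept
#' streamlines form the tract probability map.
#'
#' @param field a `thala_orientation`.
#' @param seed binary seed mask (e.g. the dentate nucleus contralateral to
#'   the thalamus).
#' @param spec a [waypoint_spec()].
#' @param params a [tracking_params()].
#' @param master_seed integer RNG seed.
#' @param keep_streamlines return the kept streamline polylines.
#' @return object of class `thala_tract`: `map` (`thala_volume` visitation
#'   counts), `n_kept`, `n_launched`, `waytotal` (= `n_kept`),
#'   `streamlines` (list of n x 3 matrices, if kept), `reasons`.
#' @export
track_waypoint_tract <- function(field, seed, spec,
                                 params = tracking_params(),
                                 master_seed = 1L,
                                 keep_streamlines = TRUE) {
  stopifnot(inherits(spec, "waypoint_spec"))
  sv <- mask_indices(seed)
  if (nrow(sv) == 0) stop("empty seed mask")
  n <- dim(field$kappa)
  wl <- array(0L, n)
  for (w in seq_along(spec$waypoints)) {
    m <- as.logical(spec$waypoints[[w]]$data)
    wl[m & wl == 0L] <- w
  }
  term <- array(as.integer(as.logical(spec$target$data)), n)
  fa <- field_args(field)
  res <- track_cpp(sv - 1L, fa$dir1, fa$dir2, fa$frac1, fa$kappa, fa$mask,
                   fa$dims, fa$ainv, fa$afwd,
                   integer(0), 0L,
                   as.integer(wl), length(spec$waypoints),
                   as.integer(term), 1L,
                   params$samples_per_seed_voxel, params$seed_jitter,
                   resolve_step(params, field),
                   cos(params$curvature_limit_deg * pi / 180),
                   params$max_steps, as.integer(master_seed),
                   keep_streamlines, TRUE)
  structure(list(map = volume(array(res$visitation, n),
                              affine = field$affine),
                 n_kept = res$waytotal,
                 n_launched = nrow(sv) * params$samples_per_seed_voxel,
                 waytotal = res$waytotal,
                 streamlines = if (keep_streamlines) res$streamlines,
                 reasons = stats::setNames(as.integer(res$reasons),
                                           .termination_reasons)),
            class = "thala_tract")
}

#' @export
print.thala_tract <- function(x, ...) {
  cat(sprintf("<thala_tract> kept %s of %s samples\n",
              format(x$n_kept), format(x$n_launched)))
  invisible(x)
}

#' Convenience builder for the cerebello-thalamic way-point run
#'
#' Seeds from the dentate nucleus contralateral to the targeted thalamus,
#' with ordered way-points: the superior cerebellar peduncle contralateral
#' to the thalamus, then the red nucleus ipsilateral to the thalamus
#' dilated by `dilate_red_nucleus` voxels; the terminal target is the
#' thalamus itself.
#'
#' @param labels phantom `thala_labels` (atlas or subject instance).
#' @param side `"l"` or `"r"`: the thalamus side the tract feeds.
#' @param dilate_red_nucleus dilation iterations for the red nucleus mask.
#' @return list with `seed` (dentate mask) and `spec` (a [waypoint_spec()]).
#' @export
ctt_waypoint_spec <- function(labels, side = c("l", "r"),
                              dilate_red_nucleus = 4L) {
  side <- match.arg(side)
  contra <- if (side == "l") "r" else "l"
  list(seed = label_mask(labels, paste0("dentate_", contra)),
       spec = waypoint_spec(
         waypoints = list(
           scp = label_mask(labels, paste0("scp_", contra)),
           red_nucleus = dilate_mask(
             label_mask(labels, paste0("red_nucleus_", side)),
             dilate_red_nucleus)),
         target = label_mask(labels, paste0("thalamus_", side))))
}

#' Binary morphological dilation (6-connected, iterated)
#'
#' @param mask binary `thala_volume` (or logical/numeric array).
#' @param iterations number of dilation passes (>= 0).
#' @return same type as the input.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  stopifnot(iterations >= 0)
  is_vol <- inherits(mask, "thala_volume")
  m <- if (is_vol) mask$data != 0 else mask != 0
  n <- dim(m)
  for (it in seq_len(iterations)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-n[1], , ]
    out[-n[1], , ] <- out[-n[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -n[2], ]
    out[, -n[2], ] <- out[, -n[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -n[3]]
    out[, , -n[3]] <- out[, , -n[3]] | m[, , -1]
    m <- out
  }
  if (is_vol) volume(m, affine = mask$affine) else m
}

#' Write kept streamlines as JSON lines
#'
#' One JSON object per line: `{"id": i, "points": [[x,y,z], ...]}` in world
#' mm, a documented plain-text alternative to binary tract formats.
#'
#' @param tract a `thala_tract` with stored streamlines.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_streamlines_json <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(tract$streamlines)) {
    writeLines(jsonlite::toJSON(
      list(id = i, points = unname(tract$streamlines[[i]])),
      auto_unbox = TRUE, digits = 4), con)
  }
  invisible(path)
}
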