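#' Seed and target definitions for the intra-thalamic intents
#'
#' Three connectivity-based targets are mapped per hemisphere, each seeded
#' from the entire thalamus of that side: `"vlpv"` (targets: precentral
#' gyrus, supplementary motor area and the contralateral cerebellum),
#' `"precentral"` (precentral gyrus only) and `"postcentral"` (postcentral
#' gyrus only). The atlas reference is the VLpv nucleus for the first two
#' intents and the VPLp nucleus for the postcentral connections.
#'
#' @param labels a phantom `thala_labels` (atlas or subject instance).
#' @param intent one of `"vlpv"`, `"precentral"`, `"postcentral"`.
#' @param side `"l"` or `"r"`.
#' @return list with `seed` (mask), `targets` (named mask list) and
#'   `atlas_name` (the reference region name).
#' @export
intent_spec <- function(labels, intent = c("vlpv", "precentral",
                                           "postcentral"),
                        side = c("l", "r")) {
  intent <- match.arg(intent)
  side <- match.arg(side)
  contra <- if (side == "l") "r" else "l"
  seed <- label_mask(labels, paste0("thalamus_", side))
  targets <- switch(intent,
    vlpv = list(
      precentral = label_mask(labels, paste0("precentral_", side)),
      sma = label_mask(labels, paste0("sma_", side)),
      cerebellum = label_mask(labels, paste0("cerebellum_", contra,
                                             "_full"))),
    precentral = list(
      precentral = label_mask(labels, paste0("precentral_", side))),
    postcentral = list(
      postcentral = label_mask(labels, paste0("postcentral_", side))))
  atlas_name <- switch(intent,
    vlpv = paste0("vlpv_", side),
    precentral = paste0("vlpv_", side),
    postcentral = paste0("vplp_", side))
  list(seed = seed, targets = targets, atlas_name = atlas_name)
}

#' Run the full phantom study end to end
#'
#' Generates the phantom set, tracks every (intent, side, subject, scanner)
#' combination, normalizes by waytotal, sweeps the percentile grid against
#' the atlas targets, selects per-(intent, side) optimal thresholds by the
#' product-of-medians consensus rule, decomposes reproducibility at those
#' optima, and analyses the cerebello-thalamic tract in the AC-PC slab at
#' a fixed percentile. The whole run is a pure function of the
#' configuration and `master_seed`.
#'
#' @param config a [phantom_config()].
#' @param params a [tracking_params()]; the default uses 200 samples per
#'   seed voxel, a reduced load suitable for phantom-scale experiments.
#' @param grid integer percentile grid.
#' @param intents intents to map.
#' @param sides hemispheres to map.
#' @param master_seed RNG seed for tracking streams.
#' @param test difference test for the reproducibility decomposition.
#' @param ctt_percentile fixed percentile for the tract analysis.
#' @param ctt_half_extent_mm slab half-thickness around the AC-PC plane.
#' @param run_ctt include the cerebello-thalamic tract analysis.
#' @return object of class `thala_study`: `records` (tidy per-unit sweep
#'   tibble), `optima`, `table2` (Table-2-shaped reproducibility tibble),
#'   `repro` (list of `thala_repro`), `maps` (unit map tibble), `config`.
#' @export
run_study <- function(config = phantom_config(),
                      params = tracking_params(samples_per_seed_voxel = 200),
                      grid = 50:100,
                      intents = c("vlpv", "precentral", "postcentral"),
                      sides = c("l", "r"),
                      master_seed = config$master_seed,
                      test = c("welch", "permutation"),
                      ctt_percentile = 90,
                      ctt_half_extent_mm = 20,
                      run_ctt = TRUE) {
  test <- match.arg(test)
  atlas <- generate_atlas(config)
  design <- tidyr::expand_grid(subject = seq_len(config$n_subjects),
                               scanner = seq_len(config$n_scanners))

  map_rows <- list()
  ctt_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    subj <- generate_subject(atlas, s, config)
    for (sc in seq_len(config$n_scanners)) {
      field <- apply_scanner(subj$field, sc, config)
      for (side in sides) {
        for (intent in intents) {
          sp <- intent_spec(subj$labels, intent, side)
          cm <- track_seed_mask(field, sp$seed, sp$targets, params,
                                master_seed = derive_seed(
                                  master_seed, s, sc,
                                  match(intent, intents), match(side, sides)))
          cm <- normalize_by_waytotal(cm)
          map_rows[[length(map_rows) + 1]] <- tibble::tibble(
            intent = intent, side = side, subject = s, scanner = sc,
            map = list(cmap_volume(cm)))
        }
        if (run_ctt) {
          ct <- ctt_waypoint_spec(subj$labels, side)
          tr <- track_waypoint_tract(field, ct$seed, ct$spec, params,
                                     master_seed = derive_seed(
                                       master_seed, s, sc, 9L,
                                       match(side, sides)),
                                     keep_streamlines = FALSE)
          ctt_rows[[length(ctt_rows) + 1]] <- tibble::tibble(
            intent = "ctt", side = side, subject = s, scanner = sc,
            map = list(tr$map))
        }
      }
    }
  }
  maps <- dplyr::bind_rows(map_rows)
  ctt_maps <- dplyr::bind_rows(ctt_rows)

  atlas_targets <- list()
  for (intent in intents) for (side in sides) {
    sp <- intent_spec(atlas, intent, side)
    atlas_targets[[paste(intent, side, sep = "_")]] <-
      label_mask(atlas, sp$atlas_name)
  }

  records <- dplyr::bind_rows(purrr::pmap(maps, function(intent, side,
                                                         subject, scanner,
                                                         map) {
    sw <- sweep_thresholds(map,
                           atlas_targets[[paste(intent, side, sep = "_")]],
                           grid = grid, intent = intent)
    sw$side <- side; sw$subject <- subject; sw$scanner <- scanner
    sw[, c("intent", "side", "subject", "scanner", "percentile",
           "dice", "cog_mm", "vol_x", "vol_y", "degenerate")]
  }))

  optima <- optimize_all(maps, atlas_targets, grid = grid)

  repro <- list()
  for (r in seq_len(nrow(optima))) {
    it <- optima$intent[r]; sd_ <- optima$side[r]
    popt <- optima$optimal_percentile[r]
    sub <- maps[maps$intent == it & maps$side == sd_, ]
    units <- sub[, c("subject", "scanner")]
    units$cbt <- purrr::map(sub$map, function(m) {
      v <- m$data[m$data > 0]
      if (length(v) == 0) return(volume(array(FALSE, dim(m$data)),
                                        affine = m$affine))
      percentile_threshold(m, popt, intent = it)
    })
    pr <- pairwise_dice(units, intent = it, side = sd_)
    repro[[paste(it, sd_, sep = "_")]] <-
      decompose_variability(pr, test = test, cbt_units = units)
  }
  if (run_ctt && nrow(ctt_maps) > 0) {
    for (side in sides) {
      sub <- ctt_maps[ctt_maps$side == side, ]
      repro[[paste("ctt", side, sep = "_")]] <- ctt_reproducibility(
        sub, acpc_z_mm = atlas$acpc_z_mm, percentile = ctt_percentile,
        half_extent_mm = ctt_half_extent_mm, side = side, test = test)
    }
  }
  table2 <- dplyr::bind_rows(purrr::map(repro, glance))

  structure(list(records = records,
                 optima = optima[, c("intent", "side", "optimal_percentile",
                                     "product_max")],
                 consensus = stats::setNames(
                   optima$consensus, paste(optima$intent, optima$side,
                                           sep = "_")),
                 table2 = table2, repro = repro,
                 maps = maps, ctt_maps = ctt_maps,
                 atlas_targets = atlas_targets,
                 acpc_z_mm = atlas$acpc_z_mm,
                 config = config),
            class = "thala_study")
}

#' @export
print.thala_study <- function(x, ...) {
  cat(sprintf(
    "<thala_study> %d subject(s) x %d scanner(s); %d evaluation records\n",
    x$config$n_subjects, x$config$n_scanners, nrow(x$records)))
  print(x$optima)
  invisible(x)
}

#' Write the study outputs as tidy CSV files
#'
#' Writes `records.csv` (per-unit percentile sweeps), `optima.csv`
#' (optimal percentile per intent and side) and `table2.csv` (the
#' reproducibility decomposition). Output is deterministic: identical
#' studies produce byte-identical files.
#'
#' @param study a `thala_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    df <- as.data.frame(df)
    for (cl in names(df)) {
      if (is.numeric(df[[cl]])) df[[cl]] <- format(df[[cl]], digits = 10,
                                                   trim = TRUE,
                                                   scientific = FALSE)
    }
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(study$records, "records.csv")
  wr(study$optima, "optima.csv")
  wr(study$table2, "table2.csv")
  invisible(dir)
}

#' Simulate exchangeable CBT units without tractography
#'
#' A light-weight generator for calibration studies of the reproducibility
#' decomposition: each (subject, scanner) unit is a spherical CBT whose
#' centre is displaced by the sum of a systematic subject effect, a
#' systematic scanner effect and independent per-scan noise, all isotropic
#' Gaussian with the given magnitudes (mm). With zero systematic effects
#' the units are fully exchangeable, giving a null for type-I calibration
#' of the group-difference test; a large scanner effect produces the
#' generative asymmetry recovered by [decompose_variability()].
#'
#' @param n_subjects,n_scanners design size.
#' @param subject_effect_mm SD of the per-subject systematic displacement.
#' @param scanner_effect_mm SD of the per-scanner systematic displacement.
#' @param scan_noise_mm SD of the independent per-scan displacement.
#' @param radius_mm sphere radius.
#' @param grid_shape,voxel_size_mm grid of the simulated CBTs.
#' @param seed RNG seed.
#' @return tibble: `subject`, `scanner`, `cbt` (list of binary
#'   `thala_volume`s).
#' @export
simulate_cbt_units <- function(n_subjects, n_scanners,
                               subject_effect_mm = 0,
                               scanner_effect_mm = 0,
                               scan_noise_mm = 1,
                               radius_mm = 5,
                               grid_shape = c(24L, 24L, 24L),
                               voxel_size_mm = c(1, 1, 1),
                               seed = 1L) {
  set.seed(seed)
  aff <- diag(c(voxel_size_mm, 1))
  center <- (grid_shape - 1) / 2 * voxel_size_mm
  u <- matrix(stats::rnorm(3 * n_subjects, 0, subject_effect_mm),
              n_subjects, 3)
  t_ <- matrix(stats::rnorm(3 * n_scanners, 0, scanner_effect_mm),
               n_scanners, 3)
  ii <- (seq_len(grid_shape[1]) - 1) * voxel_size_mm[1]
  jj <- (seq_len(grid_shape[2]) - 1) * voxel_size_mm[2]
  kk <- (seq_len(grid_shape[3]) - 1) * voxel_size_mm[3]
  out <- tidyr::expand_grid(subject = seq_len(n_subjects),
                            scanner = seq_len(n_scanners))
  out$cbt <- purrr::map2(out$subject, out$scanner, function(s, c) {
    e <- stats::rnorm(3, 0, scan_noise_mm)
    ctr <- center + u[s, ] + t_[c, ] + e
    d2 <- outer(outer((ii - ctr[1])^2, (jj - ctr[2])^2, "+"),
                (kk - ctr[3])^2, "+")
    volume(array(d2 <= radius_mm^2, grid_shape), affine = aff)
  })
  out
}
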