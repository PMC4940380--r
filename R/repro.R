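#' Pairwise Dice overlaps across (subject, scanner) units
#'
#' Computes the Dice overlap for every unordered pair of units and tags
#' each pair: `inter_scanner` (same subject, different scanner),
#' `inter_subject` (different subject, same scanner) or `crossed` (both
#' differ). Units with a degenerate (empty) CBT are excluded and counted.
#'
#' @param cbts tibble with columns `subject`, `scanner` and `cbt`
#'   (list-column of binary `thala_volume`s, typically built at the
#'   intent's optimal percentile).
#' @param intent,side optional labels carried into the output.
#' @return tibble of class `thala_pairs`: `subject_a`, `scanner_a`,
#'   `subject_b`, `scanner_b`, `dice`, `group`; attribute `n_excluded`.
#' @export
pairwise_dice <- function(cbts, intent = NA_character_,
                          side = NA_character_) {
  stopifnot(all(c("subject", "scanner", "cbt") %in% names(cbts)))
  if (nrow(cbts) < 2) stop("need at least 2 units")
  arrs <- lapply(cbts$cbt, as_binary_array)
  sizes <- vapply(arrs, sum, numeric(1))
  ok <- sizes > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " unit(s) with degenerate CBT excluded")
  keep <- which(ok)
  if (length(keep) < 2) stop("fewer than 2 non-degenerate units")
  pr <- utils::combn(keep, 2)
  rows <- purrr::map(seq_len(ncol(pr)), function(p) {
    a <- pr[1, p]; b <- pr[2, p]
    same_sub <- cbts$subject[a] == cbts$subject[b]
    same_scan <- cbts$scanner[a] == cbts$scanner[b]
    tibble::tibble(
      intent = intent, side = side,
      subject_a = cbts$subject[a], scanner_a = cbts$scanner[a],
      subject_b = cbts$subject[b], scanner_b = cbts$scanner[b],
      dice = 2 * sum(arrs[[a]] & arrs[[b]]) / (sizes[a] + sizes[b]),
      group = if (same_sub && !same_scan) "inter_scanner"
      else if (!same_sub && same_scan) "inter_subject"
      else "crossed")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("thala_pairs", class(out))
  out
}

# Welch p-value with a constant-data guard: identical constant groups give
# p = 1, constant but different groups p ~ 0
welch_p <- function(x, y) {
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

# permutation test on the group-mean difference, permuting unit labels so
# the dependence between pairs sharing a unit is preserved
permutation_p <- function(cbt_units, dice_mat, n_perm, perm_seed) {
  n <- nrow(cbt_units)
  grp <- matrix(0L, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    same_sub <- cbt_units$subject[a] == cbt_units$subject[b]
    same_scan <- cbt_units$scanner[a] == cbt_units$scanner[b]
    g <- if (same_sub && !same_scan) 1L
    else if (!same_sub && same_scan) 2L else 0L
    grp[a, b] <- g; grp[b, a] <- g
  }
  stat <- function(perm) {
    gp <- grp[perm, perm]
    up <- upper.tri(gp)
    mean(dice_mat[up][gp[up] == 1L]) - mean(dice_mat[up][gp[up] == 2L])
  }
  obs <- stat(seq_len(n))
  set.seed(perm_seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(stat(sample.int(n))) >= abs(obs) - 1e-15) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

#' Decompose CBT variability into scanner and subject components
#'
#' Summarizes the tagged pairwise Dice values: group means and SDs for the
#' within-subject inter-scanner and inter-subject within-scanner pairs, a
#' two-sided test of their difference, and the overall mean and SD across
#' all pairs (crossed pairs included in the overall figures only).
#'
#' The default test is a Welch two-sample t-test on the two groups' Dice
#' values. Pairwise Dice values sharing a unit are not independent; a
#' permutation alternative that permutes unit labels (and therefore
#' preserves that dependence) is available via `test = "permutation"`.
#'
#' @param pairs a `thala_pairs` tibble from [pairwise_dice()].
#' @param test `"welch"` or `"permutation"`.
#' @param n_perm number of permutations for the permutation test.
#' @param perm_seed RNG seed for the permutation test.
#' @param cbt_units the unit table (`subject`, `scanner`) used to build
#'   `pairs`; required for `test = "permutation"` (reconstructed from the
#'   pairs when omitted).
#' @return object of class `thala_repro`; see [glance.thala_repro()] for
#'   the one-row summary.
#' @export
decompose_variability <- function(pairs, test = c("welch", "permutation"),
                                  n_perm = 2000L, perm_seed = 1L,
                                  cbt_units = NULL) {
  test <- match.arg(test)
  gs <- pairs$dice[pairs$group == "inter_scanner"]
  gb <- pairs$dice[pairs$group == "inter_subject"]
  incomplete <- length(gs) < 2 || length(gb) < 2
  p <- NA_real_
  if (!incomplete) {
    if (test == "welch") {
      p <- welch_p(gs, gb)
    } else {
      if (is.null(cbt_units)) cbt_units <- units_from_pairs(pairs)
      dice_mat <- dice_matrix_from_pairs(pairs, cbt_units)
      p <- permutation_p(cbt_units, dice_mat, n_perm, perm_seed)
    }
  }
  summary <- tibble::tibble(
    intent = pairs$intent[1], side = pairs$side[1],
    inter_scanner_mean = mean(gs), inter_scanner_sd = stats::sd(gs),
    inter_subject_mean = mean(gb), inter_subject_sd = stats::sd(gb),
    p_value = p,
    overall_mean = mean(pairs$dice), overall_sd = stats::sd(pairs$dice),
    n_inter_scanner = length(gs), n_inter_subject = length(gb),
    n_pairs = nrow(pairs), test = test,
    incomplete = incomplete)
  structure(list(pairs = pairs, summary = summary),
            class = "thala_repro")
}

units_from_pairs <- function(pairs) {
  u <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(subject = pairs$subject_a, scanner = pairs$scanner_a),
    tibble::tibble(subject = pairs$subject_b, scanner = pairs$scanner_b)))
  dplyr::arrange(u, .data$subject, .data$scanner)
}

dice_matrix_from_pairs <- function(pairs, units) {
  key <- paste(units$subject, units$scanner)
  n <- nrow(units)
  m <- matrix(NA_real_, n, n)
  ia <- match(paste(pairs$subject_a, pairs$scanner_a), key)
  ib <- match(paste(pairs$subject_b, pairs$scanner_b), key)
  m[cbind(ia, ib)] <- pairs$dice
  m[cbind(ib, ia)] <- pairs$dice
  m
}

#' @export
print.thala_repro <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<thala_repro> inter-scanner %.3f +/- %.3f, ",
           "inter-subject %.3f +/- %.3f, p = %s (%s)\n"),
    s$inter_scanner_mean, s$inter_scanner_sd,
    s$inter_subject_mean, s$inter_subject_sd,
    format(s$p_value, digits = 3), s$test))
  invisible(x)
}

#' @rdname decompose_variability
#' @param x a `thala_repro`.
#' @param ... unused.
#' @export
tidy.thala_repro <- function(x, ...) x$pairs

#' One-row reproducibility summary
#' @rdname decompose_variability
#' @export
glance.thala_repro <- function(x, ...) x$summary

#' Restrict a volume to an axial slab around the AC-PC plane
#'
#' Voxels whose world z satisfies `|z - acpc_z_mm| <= half_extent_mm` are
#' retained; all others are zeroed. The default half extent of 20 mm gives
#' the 40 mm subvolume used for tract evaluation.
#'
#' @param vol a `thala_volume` (probability map or CBT).
#' @param acpc_z_mm world z of the AC-PC plane.
#' @param half_extent_mm slab half-thickness in mm.
#' @return same type as `vol`.
#' @export
restrict_slab <- function(vol, acpc_z_mm, half_extent_mm = 20) {
  z <- voxel_world_z(vol)
  keep <- abs(z - acpc_z_mm) <= half_extent_mm
  if (!any(keep)) stop("slab does not intersect the volume grid")
  out <- vol
  out$data <- vol$data * keep
  if (!is.null(out$weight_data)) out$weight_data <- out$weight_data * keep
  if (!is.null(out$n_voxels)) out$n_voxels <- sum(out$data != 0)
  out
}

#' Reproducibility of the cerebello-thalamic tract
#'
#' The consensus threshold optimization is not applicable to the tract (it
#' has no atlas target), so each unit's tract probability map is first
#' restricted to the AC-PC slab and then thresholded at a fixed percentile
#' (default the 90th percentile of the slab's non-zero connection values);
#' the resulting CBTs enter [pairwise_dice()] and
#' [decompose_variability()]. The slab restriction is applied *before*
#' thresholding. Units whose slab-restricted map is empty are excluded and
#' counted.
#'
#' @param maps tibble with columns `subject`, `scanner`, `map`
#'   (list-column of tract probability `thala_volume`s from
#'   [track_waypoint_tract()]).
#' @param acpc_z_mm world z of the AC-PC plane.
#' @param percentile fixed connectivity percentile (default 90).
#' @param half_extent_mm slab half-thickness (default 20 mm).
#' @param intent,side labels for the output row.
#' @param ... passed to [decompose_variability()].
#' @return a `thala_repro`.
#' @export
ctt_reproducibility <- function(maps, acpc_z_mm, percentile = 90,
                                half_extent_mm = 20,
                                intent = "ctt", side = NA_character_, ...) {
  stopifnot(all(c("subject", "scanner", "map") %in% names(maps)))
  cbts <- purrr::map(maps$map, function(m) {
    slab <- restrict_slab(m, acpc_z_mm, half_extent_mm)
    if (all(slab$data == 0)) return(NULL)
    percentile_threshold(slab, percentile, intent = intent)
  })
  empty <- vapply(cbts, is.null, logical(1))
  if (any(empty))
    message(sum(empty), " unit(s) with empty slab-restricted map excluded")
  units <- maps[!empty, c("subject", "scanner")]
  units$cbt <- cbts[!empty]
  pairs <- pairwise_dice(units, intent = intent, side = side)
  decompose_variability(pairs, cbt_units = units, ...)
}
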