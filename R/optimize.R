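#' Median inter-subject overlap as a function of the threshold
#'
#' For every percentile of the grid, thresholds each unit's connectivity
#' map and computes all pairwise Dice overlaps between CBTs of *different
#' subjects on the same scanner*, pooled across scanner replicates; the
#' curve value is the median of those pairwise overlaps. Units whose CBT is
#' degenerate (empty) at a percentile are excluded from that percentile's
#' pairs, and the exclusion is counted.
#'
#' @param maps tibble with columns `subject`, `map` (list of
#'   `thala_volume`/`thala_cmap`) and optionally `scanner` (absent: all
#'   different-subject pairs are used).
#' @param grid integer percentiles in `[50, 100]`.
#' @return tibble of class `thala_curve`: `percentile`, `value`,
#'   `n_pairs`, `n_excluded`, with `metric = "median_intersubject_dice"`.
#' @export
intersubject_overlap_curve <- function(maps, grid = 50:100) {
  stopifnot(is.data.frame(maps), "subject" %in% names(maps))
  if (length(unique(maps$subject)) < 2)
    stop("need at least 2 subjects for inter-subject overlap")
  has_scanner <- "scanner" %in% names(maps)
  arrs <- lapply(maps$map, function(m) {
    if (inherits(m, "thala_cmap")) cmap_volume(m)$data else m$data
  })
  cuts <- lapply(arrs, function(a) {
    v <- a[a > 0]
    if (length(v) == 0) rep(NA_real_, length(grid))
    else stats::quantile(v, grid / 100, type = 7, names = FALSE)
  })
  n_units <- nrow(maps)
  pair_idx <- utils::combn(n_units, 2)
  use_pair <- vapply(seq_len(ncol(pair_idx)), function(p) {
    a <- pair_idx[1, p]; b <- pair_idx[2, p]
    maps$subject[a] != maps$subject[b] &&
      (!has_scanner || maps$scanner[a] == maps$scanner[b])
  }, logical(1))
  pair_idx <- pair_idx[, use_pair, drop = FALSE]
  rows <- purrr::map(seq_along(grid), function(gi) {
    masks <- lapply(seq_len(n_units), function(u) {
      if (is.na(cuts[[u]][gi])) NULL else arrs[[u]] >= cuts[[u]][gi]
    })
    sizes <- vapply(masks, function(m) if (is.null(m)) 0L else sum(m),
                    integer(1))
    ok <- !vapply(masks, is.null, logical(1)) & sizes > 0L
    dvals <- vapply(seq_len(ncol(pair_idx)), function(p) {
      a <- pair_idx[1, p]; b <- pair_idx[2, p]
      if (!ok[a] || !ok[b]) return(NA_real_)
      2 * sum(masks[[a]] & masks[[b]]) / (sizes[a] + sizes[b])
    }, numeric(1))
    tibble::tibble(percentile = grid[gi],
                   value = stats::median(dvals, na.rm = TRUE),
                   n_pairs = sum(!is.na(dvals)),
                   n_excluded = sum(is.na(dvals)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metric") <- "median_intersubject_dice"
  class(out) <- c("thala_curve", class(out))
  out
}

#' Median atlas overlap as a function of the threshold
#'
#' Median across units of the Dice overlap between each unit's CBT and the
#' atlas target, per percentile.
#'
#' @param maps tibble with a `map` list-column.
#' @param atlas_target binary `thala_volume`.
#' @param grid integer percentiles in `[50, 100]`.
#' @return tibble of class `thala_curve`: `percentile`, `value`, `n_units`,
#'   with `metric = "median_atlas_dice"`.
#' @export
atlas_overlap_curve <- function(maps, atlas_target, grid = 50:100) {
  stopifnot(is.data.frame(maps), "map" %in% names(maps))
  at <- as_binary_array(atlas_target)
  n_at <- sum(at)
  arrs <- lapply(maps$map, function(m) {
    if (inherits(m, "thala_cmap")) cmap_volume(m)$data else m$data
  })
  cuts <- lapply(arrs, function(a) {
    v <- a[a > 0]
    if (length(v) == 0) rep(NA_real_, length(grid))
    else stats::quantile(v, grid / 100, type = 7, names = FALSE)
  })
  rows <- purrr::map(seq_along(grid), function(gi) {
    dvals <- vapply(seq_along(arrs), function(u) {
      if (is.na(cuts[[u]][gi])) return(NA_real_)
      m <- arrs[[u]] >= cuts[[u]][gi]
      s <- sum(m)
      if (s == 0) return(NA_real_)
      2 * sum(m & at) / (s + n_at)
    }, numeric(1))
    tibble::tibble(percentile = grid[gi],
                   value = stats::median(dvals, na.rm = TRUE),
                   n_units = sum(!is.na(dvals)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metric") <- "median_atlas_dice"
  class(out) <- c("thala_curve", class(out))
  out
}

#' Consensus optimum of the connectivity threshold
#'
#' Multiplies the median inter-subject overlap curve with the median atlas
#' overlap curve and returns the percentile at which the product is
#' maximal; ties are broken toward the lowest percentile (the more
#' inclusive volume).
#'
#' @param intersubject,atlas `thala_curve` tibbles (or any data frames
#'   with `percentile` and `value`) on identical percentile grids.
#' @return object of class `thala_consensus` with `curve` (tibble:
#'   `percentile`, `intersubject`, `atlas`, `product`), `optimum`
#'   (percentile) and `product_max`.
#' @export
consensus_optimum <- function(intersubject, atlas) {
  if (!identical(as.numeric(intersubject$percentile),
                 as.numeric(atlas$percentile)))
    stop("percentile grids differ between the two curves")
  iv <- intersubject$value
  av <- atlas$value
  curve <- tibble::tibble(percentile = intersubject$percentile,
                          intersubject = iv, atlas = av,
                          product = iv * av)
  if (all(is.na(curve$product)))
    stop("product curve is all missing: no optimum")
  pmax_val <- max(curve$product, na.rm = TRUE)
  opt <- min(curve$percentile[!is.na(curve$product) &
                                curve$product == pmax_val])
  structure(list(curve = curve, optimum = opt, product_max = pmax_val),
            class = "thala_consensus")
}

#' @export
print.thala_consensus <- function(x, ...) {
  cat(sprintf(
    "<thala_consensus> optimum at p%.0f (product of medians = %.4f)\n",
    x$optimum, x$product_max))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname consensus_optimum
#' @param x a `thala_consensus`.
#' @param ... unused.
#' @export
tidy.thala_consensus <- function(x, ...) x$curve

#' @rdname consensus_optimum
#' @export
glance.thala_consensus <- function(x, ...) {
  tibble::tibble(optimal_percentile = x$optimum,
                 product_max = x$product_max)
}

#' Optimal connectivity percentile for every intent and hemisphere
#'
#' Runs the product-of-medians consensus rule separately per
#' (intent, side): the inter-subject overlap curve and the atlas overlap
#' curve are combined with [consensus_optimum()]. Intents with fewer than
#' two subjects are skipped with a warning. The returned optima are the
#' cut-offs reused by the downstream reproducibility analyses.
#'
#' @param maps tibble with columns `intent`, `side`, `subject`, `scanner`,
#'   `map` (list-column of connectivity maps).
#' @param atlas_targets named list of binary `thala_volume`s keyed
#'   `"<intent>_<side>"`.
#' @param grid integer percentiles in `[50, 100]`.
#' @return tibble: `intent`, `side`, `optimal_percentile`, `product_max`,
#'   `consensus` (list-column of `thala_consensus`).
#' @export
optimize_all <- function(maps, atlas_targets, grid = 50:100) {
  stopifnot(all(c("intent", "side", "subject", "map") %in% names(maps)))
  groups <- dplyr::distinct(maps[, c("intent", "side")])
  rows <- purrr::pmap(groups, function(intent, side) {
    sub <- maps[maps$intent == intent & maps$side == side, ]
    if (length(unique(sub$subject)) < 2) {
      warning("skipping ", intent, " ", side, ": fewer than 2 subjects")
      return(NULL)
    }
    key <- paste(intent, side, sep = "_")
    if (!key %in% names(atlas_targets))
      stop("no atlas target named ", key)
    cons <- consensus_optimum(
      intersubject_overlap_curve(sub, grid = grid),
      atlas_overlap_curve(sub, atlas_targets[[key]], grid = grid))
    tibble::tibble(intent = intent, side = side,
                   optimal_percentile = cons$optimum,
                   product_max = cons$product_max,
                   consensus = list(cons))
  })
  dplyr::bind_rows(rows)
}
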