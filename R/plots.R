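#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a percentile sweep
#'
#' Dice overlap and centre-of-gravity distance against the atlas target as
#' functions of the connectivity threshold.
#'
#' @param object a `thala_sweep` from [sweep_thresholds()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.thala_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("dice", "cog_mm"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, c("dice", "cog_mm"),
                        c("Dice overlap", "CoG distance (mm)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$percentile, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "connectivity threshold (percentile)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a consensus-optimization curve set
#'
#' Three panels: inter-subject overlap, atlas overlap and their product as
#' functions of the threshold, with the selected optimum marked.
#'
#' @param object a `thala_consensus` from [consensus_optimum()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.thala_consensus <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve,
                              c("intersubject", "atlas", "product"),
                              names_to = "panel", values_to = "value")
  long$panel <- factor(long$panel, c("intersubject", "atlas", "product"),
                       c("Inter-subject overlap (median Dice)",
                         "Atlas overlap (median Dice)",
                         "Product of medians"))
  ggplot2::ggplot(long, ggplot2::aes(.data$percentile, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$optimum, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "connectivity threshold (percentile)", y = NULL,
                  subtitle = sprintf("optimum: %.0fth percentile",
                                     object$optimum)) +
    ggplot2::theme_minimal()
}

#' Plot a reproducibility decomposition
#'
#' Pairwise Dice values by pair group (within-subject inter-scanner,
#' inter-subject within-scanner, crossed).
#'
#' @param object a `thala_repro` from [decompose_variability()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.thala_repro <- function(object, ...) {
  df <- object$pairs
  df$group <- factor(df$group,
                     c("inter_scanner", "inter_subject", "crossed"))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$dice)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "pairwise Dice overlap",
                  subtitle = sprintf("difference p = %s (%s)",
                                     format(object$summary$p_value,
                                            digits = 3),
                                     object$summary$test)) +
    ggplot2::theme_minimal()
}
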