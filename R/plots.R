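#' Plot an imprinting scan
#'
#' Log Bayes factor against rank, colored by parental direction, with the
#' tier thresholds (3, 10, 30) drawn as reference lines.
#'
#' @param object an `imprinting_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.imprinting_scan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$log_bayes_factor,
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = log(c(3, 10, 30)), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(maternal = "#c0392b",
                                            paternal = "#2c6fbb",
                                            none = "grey70")) +
    ggplot2::labs(x = "rank", y = "log Bayes factor (imprinting vs null)",
                  colour = "bias") +
    ggplot2::theme_minimal()
}

#' Plot a variant-density window profile
#'
#' @param object a `window_profile` from [sliding_window_profile()].
#' @param ... unused.
#' @return a ggplot of variant count against offset from the peak center.
#' @export
autoplot.window_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$count)) +
    ggplot2::geom_line(colour = "#2c6fbb") +
    ggplot2::geom_point(size = 0.6, colour = "#2c6fbb") +
    ggplot2::labs(x = "offset from peak center (bp)", y = "variant count") +
    ggplot2::theme_minimal()
}

#' Plot a known-gene rank-enrichment curve
#'
#' @param object a `rank_enrichment` from [rank_enrichment()].
#' @param ... unused.
#' @return a ggplot of the cumulative known-gene count with the identity
#'   line (every ranked gene known) as reference.
#' @export
autoplot.rank_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cumulative_known)) +
    ggplot2::geom_step(colour = "#c0392b") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "rank", y = "cumulative known genes") +
    ggplot2::theme_minimal()
}

#' Scatter of F1 allelic against F0 strain fold changes
#'
#' The classic divergence plot: each point is a gene at
#' (`x` = F1 allelic weighted log2 fold change,
#' `y` = F0 strain weighted log2 fold change), colored by the winning
#' model. Conserved genes sit at the origin, cis genes on the diagonal,
#' trans genes on the vertical axis.
#'
#' @param effects [estimate_effects()] output with a `winner` column.
#' @return a ggplot.
#' @export
plot_divergence <- function(effects) {
  stopifnot(all(c("x", "y", "winner") %in% names(effects)))
  df <- effects[!is.na(effects$winner), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$winner)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(
      conserved = "#e6c229", cis = "#3a923a", trans = "#c0392b",
      cis_and_trans = "#7d3c98", unclassified = "grey75")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change, F1 alleles (x)"),
                  y = expression(log[2] ~ "fold change, F0 strains (y)"),
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Bar plot of a per-peak variant count histogram
#'
#' @param histogram output of [count_histogram()] (normalized or not).
#' @return a ggplot.
#' @export
plot_count_histogram <- function(histogram) {
  ycol <- if ("mass" %in% names(histogram)) "mass" else "count"
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$n_variants, y = .data[[ycol]])) +
    ggplot2::geom_col(fill = "#2c6fbb") +
    ggplot2::labs(x = "variants per peak (central window)", y = ycol) +
    ggplot2::theme_minimal()
}
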