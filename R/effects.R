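#' Inverse-variance weighted mean
#'
#' Weights each replicate's posterior mean by the inverse of its posterior
#' variance: `sum(m/v) / sum(1/v)`. With equal variances this is the
#' arithmetic mean.
#'
#' @param means numeric vector of replicate posterior means.
#' @param variances numeric vector of matching posterior variances (> 0).
#' @return the weighted mean (scalar).
#' @export
#' @examples
#' weighted_mean(c(1, 2), c(1, 0.5))  # 5/3
weighted_mean <- function(means, variances) {
  if (length(means) == 0 || length(means) != length(variances)) {
    abort("means and variances must be non-empty and of equal length")
  }
  if (!all(is.finite(means)) || !all(is.finite(variances)) ||
      any(variances <= 0)) {
    abort("means must be finite and variances finite and positive")
  }
  w <- 1 / variances
  sum(means * w) / sum(w)
}

#' Weighted log2 fold change between two replicate series
#'
#' Difference of inverse-variance weighted means of natural-log expression
#' parameters, converted to log2: `(wmean(cast) - wmean(b6)) / ln 2`.
#'
#' @param cast_means,cast_vars Cast-side replicate means and variances
#'   (log-e).
#' @param b6_means,b6_vars B6-side replicate means and variances (log-e).
#' @return weighted log2 fold change, Cast over B6.
#' @export
#' @examples
#' weighted_log2_fold_change(c(log(2)), c(0.01), c(0), c(0.01))  # 1
weighted_log2_fold_change <- function(cast_means, cast_vars, b6_means, b6_vars) {
  (weighted_mean(cast_means, cast_vars) - weighted_mean(b6_means, b6_vars)) / log(2)
}

#' Weighted fold-change estimates for every gene
#'
#' For each polymorphic gene with complete data, computes `x`, the weighted
#' log2 fold change between the Cast and B6 alleles within the F1 hybrids
#' (both crosses pooled as allele-level replicates), and `y`, the weighted
#' log2 fold change between the Cast and B6 strains within the F0
#' homozygotes. If `classification` is supplied, the winning model is
#' joined on and genes classified `cis_and_trans` receive a subcategory
#' from [subcategorize()].
#'
#' @param measurements measurement tibble.
#' @param classification optional [classify_dataset()] result.
#' @return tibble: `gene_id`, `x`, `y`, and (when `classification` is
#'   given) `winner` and `subcategory`.
#' @export
estimate_effects <- function(measurements, classification = NULL) {
  poly <- measurements[measurements$polymorphic %||% TRUE, ]
  eff <- poly |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n_distinct(.data$group) == 6L) |>
    dplyr::summarise(
      x = weighted_log2_fold_change(
        .data$log_mean[.data$group %in% c("F1i_C", "F1r_C")],
        .data$log_sd[.data$group %in% c("F1i_C", "F1r_C")]^2,
        .data$log_mean[.data$group %in% c("F1i_B", "F1r_B")],
        .data$log_sd[.data$group %in% c("F1i_B", "F1r_B")]^2),
      y = weighted_log2_fold_change(
        .data$log_mean[.data$group == "F0_CAST"],
        .data$log_sd[.data$group == "F0_CAST"]^2,
        .data$log_mean[.data$group == "F0_B6"],
        .data$log_sd[.data$group == "F0_B6"]^2),
      .groups = "drop")
  if (!is.null(classification)) {
    eff <- dplyr::left_join(
      eff, classification$genes[, c("gene_id", "winner")], by = "gene_id")
    eff$subcategory <- ifelse(
      !is.na(eff$winner) & eff$winner == "cis_and_trans",
      subcategorize(eff$x, eff$y), NA_character_)
  }
  eff
}

#' Subcategorize combined cis-and-trans effects
#'
#' Classifies the joint action of cis and trans effects from `x` (F1
#' allelic weighted log2 fold change) and `y` (F0 strain weighted log2
#' fold change):
#' * `CIS_minus_trans` — opposite directions, cis stronger: `x*y > 0` and `|x| > |y|`
#' * `TRANS_minus_cis` — opposite directions, trans stronger: `x*y < 0`
#' * `CIS_plus_trans` — same direction, cis stronger: `x*y > 0` and `|x| < |y| < 2|x|`
#' * `TRANS_plus_cis` — same direction, trans stronger: `x*y > 0` and `|y| > 2|x|`
#'
#' Points on none of the open regions (`x*y = 0`, `|x| = |y|`, or
#' `|y| = 2|x|`) get the explicit label `"boundary"` rather than a forced
#' bin. (In the opposite-direction case the trans component `y - x`
#' overshoots the cis component, which is why `x*y < 0` alone marks trans
#' as the stronger effect.)
#'
#' @param x,y numeric vectors of weighted log2 fold changes (recycled to a
#'   common length).
#' @return character vector of subcategory labels.
#' @export
#' @examples
#' subcategorize(c(0.8, 0.5, 0.3, 0.5), c(0.4, -0.3, 0.9, 0.7))
subcategorize <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("x and y must be finite")
  }
  dplyr::case_when(
    x * y > 0 & abs(x) > abs(y) ~ "CIS_minus_trans",
    x * y < 0 ~ "TRANS_minus_cis",
    x * y > 0 & abs(x) < abs(y) & abs(y) < 2 * abs(x) ~ "CIS_plus_trans",
    x * y > 0 & abs(y) > 2 * abs(x) ~ "TRANS_plus_cis",
    TRUE ~ "boundary"
  )
}

SUBCATEGORIES <- c("CIS_minus_trans", "TRANS_minus_cis",
                   "CIS_plus_trans", "TRANS_plus_cis")

#' Summarize subcategory counts and the stabilizing fraction
#'
#' Opposite-direction subcategories (`CIS_minus_trans`, `TRANS_minus_cis`)
#' stabilize gene expression; same-direction subcategories shift it
#' further. Fractions are taken over assignable genes (boundary cases are
#' reported but not assigned).
#'
#' @param subcategory character vector of [subcategorize()] labels, or a
#'   tibble with a `subcategory` column (as from [estimate_effects()];
#'   `NA` rows are dropped).
#' @return one-row tibble with per-subcategory counts, `n_assignable`,
#'   `n_boundary`, `stabilizing_fraction` and `destabilizing_fraction`
#'   (`NA` when no gene is assignable).
#' @export
#' @examples
#' summarize_subcategories(rep(c("CIS_minus_trans", "TRANS_plus_cis"), c(3, 1)))
summarize_subcategories <- function(subcategory) {
  if (is.data.frame(subcategory)) subcategory <- subcategory$subcategory
  subcategory <- subcategory[!is.na(subcategory)]
  counts <- table(factor(subcategory, levels = c(SUBCATEGORIES, "boundary")))
  n_assign <- sum(counts[SUBCATEGORIES])
  stab <- counts[["CIS_minus_trans"]] + counts[["TRANS_minus_cis"]]
  tibble::tibble(
    CIS_minus_trans = counts[["CIS_minus_trans"]],
    TRANS_minus_cis = counts[["TRANS_minus_cis"]],
    CIS_plus_trans = counts[["CIS_plus_trans"]],
    TRANS_plus_cis = counts[["TRANS_plus_cis"]],
    n_boundary = counts[["boundary"]],
    n_assignable = n_assign,
    stabilizing_fraction = if (n_assign > 0) stab / n_assign else NA_real_,
    destabilizing_fraction = if (n_assign > 0) 1 - stab / n_assign else NA_real_
  )
}
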