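#' Tidy a classification result
#'
#' @param x an `ase_classification` from [classify_dataset()].
#' @param ... unused.
#' @return the per-gene tibble (marginals, posteriors, winner, exclusion
#'   reason, imprinting Bayes factor).
#' @export
tidy.ase_classification <- function(x, ...) x$genes

#' @rdname tidy.ase_classification
#' @export
glance.ase_classification <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_confident = x$n_confident,
    n_conserved = x$counts[["conserved"]],
    n_cis = x$counts[["cis"]],
    n_trans = x$counts[["trans"]],
    n_cis_and_trans = x$counts[["cis_and_trans"]],
    prop_conserved = x$proportions[["conserved"]],
    prop_cis = x$proportions[["cis"]],
    prop_trans = x$proportions[["trans"]],
    prop_cis_and_trans = x$proportions[["cis_and_trans"]],
    n_excluded_imprinted = sum(x$genes$excluded_reason == "imprinted_bf_gt_3"),
    n_excluded_nonpolymorphic = sum(x$genes$excluded_reason == "nonpolymorphic"),
    n_low_confidence = sum(x$genes$excluded_reason == "low_confidence")
  )
}

#' Tidy an imprinting scan
#'
#' @param x an `imprinting_scan` from [classify_imprinting()].
#' @param ... unused.
#' @return plain tibble of ranked imprinting calls.
#' @export
tidy.imprinting_scan <- function(x, ...) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' @rdname tidy.imprinting_scan
#' @export
glance.imprinting_scan <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_extreme = sum(x$tier == "extreme"),
    n_high = sum(x$tier %in% c("extreme", "high")),
    n_excluded = sum(x$bayes_factor > 3),
    n_maternal = sum(x$direction == "maternal"),
    n_paternal = sum(x$direction == "paternal")
  )
}

#' Tidy a tissue comparison
#'
#' @param x a `tissue_comparison` from [compare_tissues()].
#' @param ... unused.
#' @return per-gene tibble of winners, effects and sharing status.
#' @export
tidy.tissue_comparison <- function(x, ...) x$genes

#' @rdname tidy.tissue_comparison
#' @export
glance.tissue_comparison <- function(x, ...) {
  tibble::tibble(
    cis_shared = x$cis$n_shared,
    cis_specific = x$cis$n_specific_a + x$cis$n_specific_b,
    cis_fraction_tissue_specific = x$cis$fraction_tissue_specific,
    trans_shared = x$trans$n_shared,
    trans_specific = x$trans$n_specific_a + x$trans$n_specific_b,
    trans_fraction_tissue_specific = x$trans$fraction_tissue_specific,
    cis_pearson_r_F0 = x$cor_cis[["pearson_r_F0"]],
    cis_pearson_r_F1 = x$cor_cis[["pearson_r_F1"]],
    trans_pearson_r_F0 = x$cor_trans[["pearson_r_F0"]],
    trans_pearson_r_F1 = x$cor_trans[["pearson_r_F1"]]
  )
}
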