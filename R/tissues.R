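#' Compare cis and trans effects between two tissues
#'
#' Applies the comparability rule: a gene enters the cis comparison only if
#' it is classified cis in one tissue and conserved-or-cis in the other
#' (and symmetrically for trans). Genes classified, say, cis in one tissue
#' and trans in the other are excluded from both comparisons, which guards
#' against mistaking tissue-specific expression for tissue-specific
#' regulation. For genes shared in a category, the Pearson correlation of
#' the weighted log2 fold changes between tissues is reported separately
#' for the F0-based (`y`) and F1-based (`x`) values.
#'
#' @param class_a,class_b [classify_dataset()] results for tissues A and B.
#' @param effects_a,effects_b matching [estimate_effects()] tables.
#' @return object of class `tissue_comparison`: list with `genes` (per-gene
#'   winners and effects in both tissues plus `cis_status` / `trans_status`
#'   in {shared, specific_a, specific_b, excluded}), `cis`, `trans`
#'   (count summaries incl. `fraction_tissue_specific`), `cor_cis`,
#'   `cor_trans` (Pearson r of x and y for shared genes).
#' @export
compare_tissues <- function(class_a, class_b, effects_a, effects_b) {
  wa <- class_a$genes[, c("gene_id", "winner")]
  wb <- class_b$genes[, c("gene_id", "winner")]
  if (anyDuplicated(wa$gene_id) || anyDuplicated(wb$gene_id)) {
    abort("gene id collisions within a tissue's classification")
  }
  genes <- dplyr::inner_join(wa, wb, by = "gene_id",
                             suffix = c("_a", "_b")) |>
    dplyr::left_join(dplyr::rename(effects_a[, c("gene_id", "x", "y")],
                                   x_a = "x", y_a = "y"), by = "gene_id") |>
    dplyr::left_join(dplyr::rename(effects_b[, c("gene_id", "x", "y")],
                                   x_b = "x", y_b = "y"), by = "gene_id")

  status <- function(a, b, effect) {
    dplyr::case_when(
      a == effect & b == effect ~ "shared",
      a == effect & b == "conserved" ~ "specific_a",
      b == effect & a == "conserved" ~ "specific_b",
      TRUE ~ "excluded"
    )
  }
  genes$cis_status <- status(genes$winner_a, genes$winner_b, "cis")
  genes$trans_status <- status(genes$winner_a, genes$winner_b, "trans")

  summarize_sharing <- function(st) {
    n_shared <- sum(st == "shared")
    n_spec <- sum(st %in% c("specific_a", "specific_b"))
    tibble::tibble(
      n_shared = n_shared,
      n_specific_a = sum(st == "specific_a"),
      n_specific_b = sum(st == "specific_b"),
      n_comparable = n_shared + n_spec,
      fraction_tissue_specific = if (n_shared + n_spec > 0) {
        n_spec / (n_shared + n_spec)
      } else {
        NA_real_
      })
  }
  shared_cor <- function(st) {
    sh <- genes[st == "shared" & stats::complete.cases(
      genes[, c("x_a", "x_b", "y_a", "y_b")]), ]
    if (nrow(sh) < 3) {
      return(c(pearson_r_F0 = NA_real_, pearson_r_F1 = NA_real_))
    }
    c(pearson_r_F0 = cor(sh$y_a, sh$y_b),
      pearson_r_F1 = cor(sh$x_a, sh$x_b))
  }
  structure(
    list(genes = genes,
         cis = summarize_sharing(genes$cis_status),
         trans = summarize_sharing(genes$trans_status),
         cor_cis = shared_cor(genes$cis_status),
         cor_trans = shared_cor(genes$trans_status)),
    class = "tissue_comparison"
  )
}

#' @export
print.tissue_comparison <- function(x, ...) {
  cat("Cross-tissue effect sharing\n")
  cat(sprintf("  cis:   %d shared, %d + %d specific (%.0f%% tissue-specific)\n",
              x$cis$n_shared, x$cis$n_specific_a, x$cis$n_specific_b,
              100 * x$cis$fraction_tissue_specific))
  cat(sprintf("  trans: %d shared, %d + %d specific (%.0f%% tissue-specific)\n",
              x$trans$n_shared, x$trans$n_specific_a, x$trans$n_specific_b,
              100 * x$trans$fraction_tissue_specific))
  cat(sprintf("  shared-cis r: F0 %.2f, F1 %.2f\n",
              x$cor_cis[["pearson_r_F0"]], x$cor_cis[["pearson_r_F1"]]))
  invisible(x)
}
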