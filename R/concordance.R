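#' Pairwise replicate concordance on the FPKM scale
#'
#' Exponentiates the log-expression means to FPKM-equivalent units and
#' returns the Pearson correlation matrix between samples
#' (`group:replicate` columns, genes as observations). Samples with zero
#' variance yield `NA` correlations with a warning rather than an error.
#'
#' @param measurements measurement tibble.
#' @param groups optional subset of group labels to include (e.g.
#'   `c("F0_B6", "F0_CAST")` for the F0 concordance table).
#' @return symmetric correlation matrix with unit diagonal, sample labels
#'   `group:replicate`.
#' @export
replicate_concordance <- function(measurements, groups = NULL) {
  m <- measurements
  if (!is.null(groups)) m <- m[m$group %in% groups, ]
  wide <- m |>
    dplyr::mutate(sample = paste0(.data$group, ":R", .data$replicate),
                  fpkm = exp(.data$log_mean)) |>
    dplyr::select("gene_id", "sample", "fpkm") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fpkm") |>
    dplyr::select(-"gene_id") |>
    as.matrix()
  if (ncol(wide) < 2) abort("need at least 2 samples for concordance")
  degenerate <- apply(wide, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(degenerate)) {
    warn(paste0("zero-variance sample(s): ",
                toString(colnames(wide)[degenerate]),
                "; their correlations are NA"))
  }
  suppressWarnings(cor(wide, use = "pairwise.complete.obs",
                       method = "pearson"))
}

#' Enrichment of a known gene set along a ranking
#'
#' Computes the cumulative count of known genes (e.g. database-listed
#' imprinted genes) as a function of rank. The curve is monotone
#' non-decreasing; a ranking enriched for known genes at the top rises
#' steeply before flattening.
#'
#' @param ranked_gene_ids character vector of gene ids ordered by
#'   decreasing evidence (rank 1 first); duplicates are an error.
#' @param known tibble with `gene_id` and optionally `database_score`
#'   (0-4), or a plain character vector of known gene ids.
#' @param tier_size optional rank cutoff at which to report the count and
#'   fraction of known genes.
#' @return tibble of class `rank_enrichment`: `rank`, `gene_id`, `known`,
#'   `cumulative_known`; when `tier_size` is given, attributes
#'   `tier_known` and `tier_fraction`.
#' @export
#' @examples
#' rank_enrichment(c("a", "b", "c"), c("a", "c"), tier_size = 2)
rank_enrichment <- function(ranked_gene_ids, known, tier_size = NULL) {
  if (anyDuplicated(ranked_gene_ids)) {
    abort("duplicate gene ids in ranking")
  }
  known_ids <- if (is.data.frame(known)) known$gene_id else known
  curve <- tibble::tibble(
    rank = seq_along(ranked_gene_ids),
    gene_id = ranked_gene_ids,
    known = ranked_gene_ids %in% known_ids
  )
  curve$cumulative_known <- cumsum(curve$known)
  out <- tibble::new_tibble(curve, class = "rank_enrichment")
  if (!is.null(tier_size)) {
    k <- sum(curve$known[seq_len(min(tier_size, nrow(curve)))])
    attr(out, "tier_size") <- tier_size
    attr(out, "tier_known") <- k
    attr(out, "tier_fraction") <- k / tier_size
  }
  out
}

#' Two-tailed Fisher exact p-value for a 2x2 table
#'
#' Exact probability-mass rule: with margins fixed, the p-value is the sum
#' of hypergeometric probabilities of all tables no more probable than the
#' observed one (with a small relative tolerance for ties). Degenerate
#' margins (an empty row or column) have no test and return `NA`.
#'
#' @param tab 2x2 integer matrix of counts.
#' @return two-tailed p-value, or `NA` for degenerate margins.
#' @export
#' @examples
#' fisher_exact_two_tailed(matrix(c(5, 0, 0, 5), 2))  # 2/252
fisher_exact_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(NA_real_)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Direction bias of expression by fold-change threshold
#'
#' For each fold-change threshold, restricts to genes whose absolute
#' weighted log2 fold change meets the threshold, tabulates
#' (flagged x Cast-higher) and tests the association with a two-tailed
#' Fisher exact test. This reproduces the "proportion Cast-higher vs CRE
#' association at increasing fold change" analysis.
#'
#' @param fold_change numeric vector of weighted log2 fold changes.
#' @param flag logical vector (e.g. regulatory-peak-associated).
#' @param thresholds positive, strictly increasing absolute-log2
#'   fold-change cutoffs.
#' @return tibble per threshold: group sizes, proportion of Cast-higher
#'   genes in the flagged and unflagged groups, and `p_value` (`NA` for
#'   degenerate margins or empty bins, which are reported, not dropped).
#' @export
direction_bias_by_foldchange <- function(fold_change, flag,
                                         thresholds = c(0, 0.5, 1, 2)) {
  stopifnot(length(fold_change) == length(flag),
            all(thresholds >= 0), !is.unsorted(thresholds, strictly = TRUE))
  purrr::map_dfr(thresholds, function(thr) {
    keep <- abs(fold_change) >= thr
    fc <- fold_change[keep]; fl <- flag[keep]
    higher <- fc > 0
    tab <- matrix(c(sum(fl & higher), sum(fl & !higher),
                    sum(!fl & higher), sum(!fl & !higher)),
                  nrow = 2, byrow = TRUE)
    tibble::tibble(
      threshold = thr,
      n_flagged = sum(fl), n_unflagged = sum(!fl),
      prop_higher_flagged = if (sum(fl)) mean(higher[fl]) else NA_real_,
      prop_higher_unflagged = if (sum(!fl)) mean(higher[!fl]) else NA_real_,
      p_value = if (length(fc)) fisher_exact_two_tailed(tab) else NA_real_
    )
  })
}
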