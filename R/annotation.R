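peak_center <- function(start, end) (start + end) %/% 2L

#' Assign regulatory peaks to genes
#'
#' Proximity rule: a peak whose center lies within a gene's span is
#' assigned to that gene; otherwise it is assigned to the gene with the
#' nearest transcriptional start site on the same chromosome. Ties
#' (equidistant TSSs, or a center contained in overlapping genes) are
#' broken deterministically toward the lexicographically smallest gene id
#' and flagged. Peaks on chromosomes without genes are reported unassigned.
#'
#' @param peaks tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes tibble with `id`, `chrom`, `strand`, `start`, `end`, `tss`.
#' @return `peaks` with added columns `center`, `assigned_gene`,
#'   `assignment` (`contained` / `nearest_tss` / `unassigned`) and
#'   `ambiguous` (tie or overlapping-containment flag).
#' @export
assign_peaks_to_genes <- function(peaks, genes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)),
            all(c("id", "chrom", "start", "end", "tss") %in% names(genes)))
  if (nrow(genes) == 0) abort("genes must be non-empty")
  peaks <- dplyr::mutate(peaks, center = peak_center(.data$start, .data$end))
  one <- function(chr, ctr) {
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) == 0) {
      return(tibble::tibble(assigned_gene = NA_character_,
                            assignment = "unassigned", ambiguous = FALSE))
    }
    inside <- g[g$start <= ctr & ctr < g$end, ]
    if (nrow(inside) > 0) {
      # overlapping genes: nearest TSS among containing genes, then id
      inside <- inside[order(abs(ctr - inside$tss), inside$id), ]
      return(tibble::tibble(assigned_gene = inside$id[1],
                            assignment = "contained",
                            ambiguous = nrow(inside) > 1))
    }
    d <- abs(ctr - g$tss)
    nearest <- g[order(d, g$id), ]
    tibble::tibble(assigned_gene = nearest$id[1],
                   assignment = "nearest_tss",
                   ambiguous = sum(d == min(d)) > 1)
  }
  res <- purrr::map2_dfr(peaks$chrom, peaks$center, one)
  n_un <- sum(res$assignment == "unassigned")
  if (n_un > 0) {
    inform(paste0(n_un, " peak(s) on chromosomes without genes left unassigned"))
  }
  dplyr::bind_cols(peaks, res)
}

#' Sliding-window variant density profile around peak centers
#'
#' Counts variants in `window`-bp windows sliding by `step` bp across the
#' `span`-bp region centered on each peak, summed over peaks. With the
#' defaults (50/25/2000) there are 79 windows and an interior variant is
#' covered by exactly two windows. Peaks whose span would run off the
#' start of the contig are excluded and counted in a message.
#'
#' @param peaks tibble with `chrom`, `start`, `end`.
#' @param variants tibble with `chrom`, `pos` (1-based).
#' @param window,step,span window width, slide step and profiled span, bp;
#'   `step` must divide `span - window`.
#' @return tibble of class `window_profile`: `offset` (window midpoint
#'   relative to the peak center, bp) and `count`.
#' @export
sliding_window_profile <- function(peaks, variants, window = 50, step = 25,
                                   span = 2000) {
  stopifnot(span %% 2 == 0, window <= span, window > 0, step > 0)
  if ((span - window) %% step != 0) {
    abort("step must divide span - window")
  }
  n_win <- (span - window) / step + 1
  win_start <- (seq_len(n_win) - 1) * step - span / 2  # relative to center
  counts <- numeric(n_win)
  peaks <- dplyr::mutate(peaks, center = peak_center(.data$start, .data$end))
  truncated <- peaks$center - span / 2 < 0
  if (any(truncated)) {
    inform(paste0(sum(truncated),
                  " peak(s) with truncated windows at contig edge excluded"))
    peaks <- peaks[!truncated, ]
  }
  for (i in seq_len(nrow(peaks))) {
    v <- variants$pos[variants$chrom == peaks$chrom[i]] - 1L  # 0-based
    rel <- v - peaks$center[i]
    rel <- rel[rel >= -span / 2 & rel < span / 2]
    for (r in rel) {
      j <- which(win_start <= r & r < win_start + window)
      counts[j] <- counts[j] + 1
    }
  }
  tibble::new_tibble(
    tibble::tibble(offset = win_start + window / 2, count = counts),
    class = "window_profile")
}

#' Variant counts in the central window of each peak
#'
#' Counts homozygous variants whose position falls in the half-open
#' central window `[center - span/2, center + span/2)` of each peak
#' (positions compared 0-based, so a variant exactly `span/2` bp right of
#' the center is excluded and one `span/2` bp left is included).
#'
#' @inheritParams sliding_window_profile
#' @param span central window width, bp (default 1000).
#' @return `peaks` with added `center` and `n_variants`.
#' @export
central_window_counts <- function(peaks, variants, span = 1000) {
  stopifnot(span > 0)
  peaks <- dplyr::mutate(peaks, center = peak_center(.data$start, .data$end))
  peaks$n_variants <- vapply(seq_len(nrow(peaks)), function(i) {
    v <- variants$pos[variants$chrom == peaks$chrom[i]] - 1L
    sum(v >= peaks$center[i] - span / 2 & v < peaks$center[i] + span / 2)
  }, numeric(1))
  peaks
}

#' Variant frequency per kilobase
#'
#' @param counts per-peak variant counts.
#' @param span window width per peak, bp.
#' @return total variants / (number of peaks x span in kb).
#' @export
#' @examples
#' variant_frequency_per_kb(rep(8.46, 1), 1000)
variant_frequency_per_kb <- function(counts, span = 1000) {
  if (length(counts) == 0) abort("zero peaks")
  sum(counts) / (length(counts) * span / 1000)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: a population of `N`
#' units of which `K` are marked, `n` drawn without replacement, `k`
#' marked draws observed. Exact tail computed with [stats::phyper()].
#'
#' @param k marked units observed in the subset.
#' @param n subset size (draws).
#' @param K marked units in the population.
#' @param N population size.
#' @return upper-tail p-value.
#' @export
#' @examples
#' hypergeom_enrichment(4, 4, 5, 10)  # 5/210
hypergeom_enrichment <- function(k, n, K, N) {
  stopifnot(k >= 0, k <= n, k <= K, n <= N, K <= N,
            all(c(k, n, K, N) == round(c(k, n, K, N))))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of variant frequency in a peak subset
#'
#' Tests whether a subset of peaks carries more variants per kb than
#' expected from the pooled frequency. Each base pair of the tabulated
#' central windows is treated as one draw unit, giving
#' `X ~ Hypergeometric(N = total bp, K = total variants, n = subset bp)`
#' and an upper tail at `k` = subset variants. (A per-kilobase draw unit
#' would put more variants than draw units in the population at realistic
#' densities; base pairs keep the hypergeometric construction valid.)
#'
#' @param subset_variants,subset_kb variant count and tabulated kb in the
#'   subset.
#' @param total_variants,total_kb variant count and tabulated kb overall.
#' @return list: `p_value`, `subset_freq`, `total_freq` (per kb).
#' @export
frequency_enrichment_test <- function(subset_variants, subset_kb,
                                      total_variants, total_kb) {
  if (subset_variants > total_variants || subset_kb > total_kb) {
    abort("inconsistent totals: subset exceeds population")
  }
  list(
    p_value = hypergeom_enrichment(subset_variants,
                                   round(subset_kb * 1000),
                                   total_variants,
                                   round(total_kb * 1000)),
    subset_freq = subset_variants / subset_kb,
    total_freq = total_variants / total_kb
  )
}

#' Histogram of per-peak variant counts
#'
#' @param counts non-negative integer per-peak variant counts.
#' @param normalize if `TRUE`, bar masses sum to 1.
#' @return tibble `n_variants`, `count` (and `mass` when normalized);
#'   empty input gives an empty histogram.
#' @export
#' @examples
#' count_histogram(c(0, 0, 1, 1, 2), normalize = TRUE)
count_histogram <- function(counts, normalize = FALSE) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (length(counts) == 0) {
    return(tibble::tibble(n_variants = integer(0), count = integer(0)))
  }
  h <- tibble::as_tibble(table(n_variants = counts), .name_repair = "minimal")
  names(h) <- c("n_variants", "count")
  h$n_variants <- as.integer(h$n_variants)
  if (normalize) h$mass <- h$count / sum(h$count)
  h
}

#' Gene-set enrichment for a binary annotation
#'
#' Hypergeometric upper-tail test of whether a gene set is enriched for an
#' annotation (e.g. association with a regulatory peak) relative to the
#' universe.
#'
#' @param gene_set character vector of gene ids (subset of the universe).
#' @param universe tibble with `gene_id` and logical `associated`.
#' @return list: `k`, `n`, `K`, `N`, `p_value`, `prop_set`,
#'   `prop_universe`.
#' @export
association_enrichment <- function(gene_set, universe) {
  stopifnot(all(c("gene_id", "associated") %in% names(universe)))
  if (nrow(universe) == 0) abort("empty universe")
  if (!all(gene_set %in% universe$gene_id)) {
    abort("gene_set must be a subset of the universe")
  }
  in_set <- universe$gene_id %in% gene_set
  k <- sum(universe$associated[in_set])
  n <- sum(in_set)
  K <- sum(universe$associated)
  N <- nrow(universe)
  list(k = k, n = n, K = K, N = N,
       p_value = hypergeom_enrichment(k, n, K, N),
       prop_set = k / n, prop_universe = K / N)
}
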