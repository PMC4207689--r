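#' Simulate a toy genome annotation matched to a simulated expression set
#'
#' Lays the simulated genes end to end on one synthetic chromosome, drops
#' 0 to `max_peaks_per_gene` regulatory peaks per gene (inside the gene
#' body or within 1 kb of the TSS), and plants homozygous variants: a
#' uniform background density genome-wide plus an elevated density inside
#' the central 1 kb of peaks belonging to genes whose true class is `cis`,
#' so that cis-linked peaks carry `cis_peak_rate_per_kb` variants per kb in
#' their central window against `background_rate_per_kb` elsewhere.
#' Peaks record the gene they were planted in (`gene_id`), which serves as
#' the assignment ground truth.
#'
#' @param truth truth tibble from [simulate_expression()] (needs `gene_id`
#'   and `class`).
#' @param gene_length,intergenic_gap gene span and gap between adjacent
#'   genes, bp.
#' @param peak_width peak span, bp (must be >= 50 and <= gene_length).
#' @param max_peaks_per_gene peaks per gene are drawn uniformly on
#'   `0:max_peaks_per_gene`.
#' @param background_rate_per_kb,cis_peak_rate_per_kb expected homozygous
#'   variants per kb genome-wide and in the central 1 kb of cis-gene peaks;
#'   `cis_peak_rate_per_kb >= background_rate_per_kb`.
#' @param indel_fraction fraction of variants emitted as 1-bp insertions
#'   rather than SNVs.
#' @param het_fraction fraction of variants written with a heterozygous
#'   genotype (these are dropped by [read_variants_vcf()], exercising the
#'   homozygosity filter).
#' @param chrom name of the synthetic chromosome.
#' @param seed integer seed.
#' @return list with tibbles `genes` (id, chrom, strand, start, end, tss;
#'   0-based half-open), `peaks` (chrom, start, end, name,
#'   replicate_support, gene_id) and `variants` (chrom, pos 1-based, ref,
#'   alt, kind, genotype_homozygous).
#' @export
simulate_annotation <- function(truth,
                                gene_length = 4000,
                                intergenic_gap = 2000,
                                peak_width = 600,
                                max_peaks_per_gene = 3,
                                background_rate_per_kb = 5,
                                cis_peak_rate_per_kb = 10,
                                indel_fraction = 0.2,
                                het_fraction = 0,
                                chrom = "chrS",
                                seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("gene_id", "class") %in% names(truth)),
            gene_length > 0, intergenic_gap >= 0,
            peak_width >= 50, peak_width <= gene_length,
            max_peaks_per_gene >= 0,
            background_rate_per_kb >= 0,
            cis_peak_rate_per_kb >= background_rate_per_kb,
            indel_fraction >= 0, indel_fraction <= 1,
            het_fraction >= 0, het_fraction < 1)
  set.seed(seed)
  n <- nrow(truth)
  pitch <- gene_length + intergenic_gap
  offset <- 2000  # margin so no window near a peak is truncated at the origin
  start <- offset + (seq_len(n) - 1L) * pitch
  end <- start + gene_length
  if (any(start[-1] < end[-n])) abort("overlapping gene spans")
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- tibble::tibble(
    id = truth$gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end - 1L)
  )
  chrom_len <- max(end) + offset

  n_peaks <- sample(0:max_peaks_per_gene, n, replace = TRUE)
  pk_gene <- rep(seq_len(n), n_peaks)
  n_pk <- length(pk_gene)
  peaks <- tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          replicate_support = character(0),
                          gene_id = character(0))
  if (n_pk > 0) {
    near_tss <- runif(n_pk) < 0.5
    body_lo <- start[pk_gene]
    body_hi <- end[pk_gene] - peak_width
    pk_start <- integer(n_pk)
    pk_start[!near_tss] <- floor(runif(sum(!near_tss), body_lo[!near_tss],
                                       body_hi[!near_tss] + 1))
    tss_anchor <- genes$tss[pk_gene]
    pk_start[near_tss] <- floor(tss_anchor[near_tss] - peak_width / 2 +
                                runif(sum(near_tss), -1000, 1000))
    pk_start <- pmax(pk_start, 1000L)
    peaks <- tibble::tibble(
      chrom = chrom,
      start = as.integer(pk_start),
      end = as.integer(pk_start + peak_width),
      name = sprintf("peak_%05d", seq_len(n_pk)),
      replicate_support = sample(c("doublehit", "singlehit"), n_pk,
                                 replace = TRUE, prob = c(0.7, 0.3)),
      gene_id = truth$gene_id[pk_gene]
    )
  }

  # background variants uniform along the chromosome
  n_bg <- rpois(1, background_rate_per_kb * chrom_len / 1000)
  pos <- if (n_bg > 0) sample.int(chrom_len, n_bg, replace = FALSE) else integer(0)
  # extra variants in the central 1 kb of peaks linked to true-cis genes,
  # topping the density up to cis_peak_rate_per_kb there
  extra_rate <- cis_peak_rate_per_kb - background_rate_per_kb
  cis_peaks <- peaks[peaks$gene_id %in% truth$gene_id[truth$class == "cis"], ]
  if (nrow(cis_peaks) > 0 && extra_rate > 0) {
    centers <- (cis_peaks$start + cis_peaks$end) %/% 2L
    n_extra <- rpois(nrow(cis_peaks), extra_rate)
    extra_pos <- unlist(purrr::map2(centers, n_extra, function(ctr, k) {
      if (k == 0) return(integer(0))
      # 1-based positions within the half-open central kb [ctr-500, ctr+500)
      sample((ctr - 500L):(ctr + 499L) + 1L, min(k, 1000L))
    }))
    pos <- c(pos, extra_pos)
  }
  pos <- sort(unique(pos))
  n_var <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  is_indel <- runif(n_var) < indel_fraction
  alt[is_indel] <- paste0(ref[is_indel], sample(bases, sum(is_indel), replace = TRUE))
  variants <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = unname(alt),
    kind = ifelse(is_indel, "indel", "snp"),
    genotype_homozygous = runif(n_var) >= het_fraction
  )
  list(genes = genes, peaks = peaks, variants = variants,
       chrom_length = chrom_len)
}
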