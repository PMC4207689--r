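toy_genes <- tibble::tibble(
  id = c("gA", "gB", "gC"),
  chrom = c("chr1", "chr1", "chr2"),
  strand = c("+", "-", "+"),
  start = c(1000L, 5000L, 100L),
  end = c(3000L, 8000L, 900L),
  tss = c(1000L, 7999L, 100L)
)

test_that("peaks assign by containment, then nearest TSS, with flagged ties", {
  peaks <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chrX"),
    start = c(1400L, 3500L, 4496L, 10L),
    end = c(1600L, 3700L, 4504L, 20L))
  res <- suppressMessages(assign_peaks_to_genes(peaks, toy_genes))
  # center 1500 inside gA
  expect_identical(res$assigned_gene[1], "gA")
  expect_identical(res$assignment[1], "contained")
  # center 3600: outside both; |3600-1000|=2600 vs |3600-7999|=4399 -> gA
  expect_identical(res$assigned_gene[2], "gA")
  expect_identical(res$assignment[2], "nearest_tss")
  # center 4500 is not equidistant to the TSSs; build an exact tie below
  expect_identical(res$assignment[3], "nearest_tss")
  # no genes on chrX
  expect_identical(res$assignment[4], "unassigned")
  expect_true(is.na(res$assigned_gene[4]))

  # exact TSS tie: two genes with TSS at +/- d from the center
  tie_genes <- tibble::tibble(
    id = c("gZ", "gY"), chrom = "chr3", strand = "+",
    start = c(0L, 2000L), end = c(500L, 2500L), tss = c(0L, 2000L))
  tie_peak <- tibble::tibble(chrom = "chr3", start = 990L, end = 1010L)
  tie <- assign_peaks_to_genes(tie_peak, tie_genes)
  expect_identical(tie$assigned_gene, "gY")  # lexicographically smallest id
  expect_true(tie$ambiguous)

  # containment in overlapping genes: contained in both, flagged
  nest_genes <- tibble::tibble(
    id = c("outer", "inner"), chrom = "chr4", strand = "+",
    start = c(0L, 400L), end = c(2000L, 700L), tss = c(0L, 400L))
  nest_peak <- tibble::tibble(chrom = "chr4", start = 480L, end = 520L)
  nest <- assign_peaks_to_genes(nest_peak, nest_genes)
  expect_identical(nest$assignment, "contained")
  expect_identical(nest$assigned_gene, "inner")  # nearest TSS among containers
  expect_true(nest$ambiguous)
  expect_error(assign_peaks_to_genes(nest_peak, toy_genes[0, ]), "non-empty")
})

test_that("sliding windows tile the span with the expected count and coverage", {
  peak <- tibble::tibble(chrom = "chr1", start = 9700L, end = 10300L)
  # center at 10000; single variant exactly at the center (0-based 10000)
  v_center <- tibble::tibble(chrom = "chr1", pos = 10001L)
  prof <- sliding_window_profile(peak, v_center)
  expect_identical(nrow(prof), 79L)  # (2000 - 50) / 25 + 1
  expect_identical(sum(prof$count), 2)  # interior variants hit 2 windows
  # the 0-based center base lies in the windows [-25, 25) and [0, 50),
  # whose midpoints are 0 and 25
  expect_identical(prof$count[prof$offset %in% c(0, 25)], c(1, 1))
  # no variants at all
  empty <- sliding_window_profile(peak, v_center[0, ])
  expect_true(all(empty$count == 0))
  # span-edge variant covered by exactly 1 window
  v_edge <- tibble::tibble(chrom = "chr1", pos = 9001L)  # 0-based 9000
  expect_identical(sum(sliding_window_profile(peak, v_edge)$count), 1)
  # truncated peak near the contig start is excluded with a message
  near0 <- tibble::tibble(chrom = "chr1", start = 100L, end = 700L)
  expect_message(p0 <- sliding_window_profile(near0, v_center), "truncated")
  expect_true(all(p0$count == 0))
  expect_error(sliding_window_profile(peak, v_center, step = 40), "divide")
})

test_that("window totals conserve per-variant coverage on random fixtures", {
  set.seed(53)
  for (i in 1:5) {
    peaks <- tibble::tibble(chrom = "c", start = sample(5000:20000, 3),
                            end = 0L)
    peaks$end <- peaks$start + 400L
    centers <- (peaks$start + peaks$end) %/% 2L
    variants <- tibble::tibble(
      chrom = "c",
      pos = sample(seq(min(centers) - 1500, max(centers) + 1500), 60,
                   replace = TRUE))
    prof <- sliding_window_profile(peaks, variants)
    expected <- sum(vapply(centers, function(ctr) {
      rel <- variants$pos - 1L - ctr
      inside <- rel >= -1000 & rel < 1000
      # interior variants covered by 2 windows of the 50/25 tiling, edge by 1
      sum(ifelse(rel[inside] < -975 | rel[inside] >= 975, 1L, 2L))
    }, integer(1)))
    expect_identical(as.integer(sum(prof$count)), expected)
  }
})

test_that("central window counts use a half-open 1 kb interval", {
  peak <- tibble::tibble(chrom = "chr1", start = 9700L, end = 10300L)
  # center 10000 (0-based); window [9500, 10500)
  variants <- tibble::tibble(
    chrom = "chr1",
    pos = c(9500L + 1L,          # center - 500: included (left edge)
            10499L + 1L,         # center + 499: included
            10500L + 1L,         # center + 500: excluded (half-open)
            9499L + 1L))         # center - 501: excluded
  counted <- central_window_counts(peak, variants)
  expect_identical(counted$n_variants, 2)
  expect_identical(central_window_counts(peak, variants[0, ])$n_variants, 0)
})

test_that("variant frequency per kb matches the printed arithmetic", {
  expect_equal(round(variant_frequency_per_kb(c(86389, rep(0, 10211))), 2), 8.46)
  expect_equal(round(variant_frequency_per_kb(c(21174, rep(0, 2184))), 2), 9.69)
  expect_equal(round(variant_frequency_per_kb(c(4068, rep(0, 486))), 2), 8.35)
  expect_equal(variant_frequency_per_kb(rep(0, 10)), 0)
  expect_error(variant_frequency_per_kb(numeric(0)), "zero peaks")
})

test_that("hypergeometric tails match enumeration on small instances", {
  expect_equal(hypergeom_enrichment(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeom_enrichment(5, 5, 10, 20), 252 / 15504)
  set.seed(59)
  for (i in 1:100) {
    N <- sample(5:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(hypergeom_enrichment(k, n, K, N), hyper_tail_enum(k, n, K, N),
                 tolerance = 1e-12)
  }
  # below-expectation counts sit in the upper half of the tail
  expect_gt(hypergeom_enrichment(1, 10, 10, 20), 0.5)
  # subset = population, all marked drawn: p = 1
  expect_equal(hypergeom_enrichment(5, 10, 5, 10), 1)
  expect_error(hypergeom_enrichment(6, 5, 10, 20))
})

test_that("frequency enrichment detects denser subsets and checks totals", {
  res <- frequency_enrichment_test(300, 20, 1500, 200)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$subset_freq, 15)
  expect_equal(res$total_freq, 7.5)
  expect_error(frequency_enrichment_test(10, 300, 5, 200), "inconsistent")
})

test_that("count histograms normalize to unit mass", {
  h <- count_histogram(c(0, 0, 1, 1, 2), normalize = TRUE)
  expect_equal(h$mass, c(0.4, 0.4, 0.2))
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  expect_identical(sum(count_histogram(c(0, 0, 1, 1, 2))$count), 5L)
  expect_identical(nrow(count_histogram(integer(0))), 0L)
})

test_that("gene-set association enrichment follows the hypergeometric", {
  universe <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                             associated = rep(c(TRUE, FALSE), each = 10))
  res <- association_enrichment(sprintf("g%02d", 1:5), universe)
  expect_equal(res$p_value, 252 / 15504)
  expect_equal(res$prop_set, 1)
  expect_equal(res$prop_universe, 0.5)
  # whole universe: p = 1
  expect_equal(association_enrichment(universe$gene_id, universe)$p_value, 1)
  # no associated genes in the set: p near 1
  res0 <- association_enrichment(sprintf("g%02d", 11:15), universe)
  expect_gt(res0$p_value, 0.9)
  expect_error(association_enrichment("nope", universe), "subset")
  expect_error(association_enrichment("g01", universe[0, ]), "empty")
})
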