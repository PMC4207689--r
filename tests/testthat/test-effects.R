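test_that("weighted mean follows the closed form", {
  expect_equal(weighted_mean(c(1, 2, 3), rep(0.4, 3)), 2)       # equal weights
  expect_equal(weighted_mean(c(1, 2), c(1, 0.5)), 5 / 3)        # hand result
  expect_equal(weighted_mean(4.2, 0.9), 4.2)                    # single value
  set.seed(2)
  for (i in 1:20) {
    m <- rnorm(5); v <- rep(runif(1, 0.1, 2), 5)
    expect_equal(weighted_mean(m, v), mean(m), tolerance = 1e-12)
  }
  expect_error(weighted_mean(numeric(0), numeric(0)), "non-empty")
  expect_error(weighted_mean(c(1, NA), c(1, 1)), "finite")
  expect_error(weighted_mean(c(1, 2), c(1, 0)), "positive")
})

test_that("weighted log2 fold change converts log-e differences", {
  expect_equal(weighted_log2_fold_change(c(1, 1), c(1, 1), c(1, 1), c(1, 1)), 0)
  expect_equal(weighted_log2_fold_change(log(2), 0.1, 0, 0.1), 1)
  expect_equal(weighted_log2_fold_change(c(1, 2), c(1, 0.5), 0, 1),
               (5 / 3) / log(2))
})

test_that("subcategorization reproduces the printed inequality examples", {
  expect_identical(subcategorize(0.8, 0.4), "CIS_minus_trans")
  expect_identical(subcategorize(0.5, -0.3), "TRANS_minus_cis")
  expect_identical(subcategorize(0.3, 0.9), "TRANS_plus_cis")   # 0.9 > 0.6
  expect_identical(subcategorize(0.5, 0.7), "CIS_plus_trans")   # 0.5<0.7<1.0
  expect_identical(subcategorize(-0.8, -0.4), "CIS_minus_trans")
  expect_identical(subcategorize(0, 0.4), "boundary")
  expect_identical(subcategorize(0.4, 0.4), "boundary")
  expect_identical(subcategorize(0.4, 0.8), "boundary")
  expect_error(subcategorize(NA_real_, 1), "finite")
})

test_that("subcategories partition the plane off the boundary sets", {
  set.seed(31)
  x <- runif(4000, -2, 2); y <- runif(4000, -2, 2)
  interior <- x * y != 0 & abs(x) != abs(y) & abs(y) != 2 * abs(x)
  lab <- subcategorize(x[interior], y[interior])
  expect_false(any(lab == "boundary"))
  # each point satisfies exactly one defining inequality system
  n_match <- (x[interior] * y[interior] > 0 & abs(x[interior]) > abs(y[interior])) +
    (x[interior] * y[interior] < 0) +
    (x[interior] * y[interior] > 0 & abs(x[interior]) < abs(y[interior]) &
       abs(y[interior]) < 2 * abs(x[interior])) +
    (x[interior] * y[interior] > 0 & abs(y[interior]) > 2 * abs(x[interior]))
  expect_true(all(n_match == 1))
})

test_that("labels are consistent with the implied trans component", {
  set.seed(37)
  x <- runif(2000, -2, 2); y <- runif(2000, -2, 2)
  lab <- subcategorize(x, y)
  t_comp <- y - x
  i <- lab == "CIS_minus_trans"
  expect_true(all(sign(t_comp[i]) == -sign(x[i]) | t_comp[i] == 0))
  expect_true(all(abs(x[i]) > abs(t_comp[i])))
  j <- lab == "TRANS_plus_cis"
  expect_true(all(sign(t_comp[j]) == sign(x[j])))
  expect_true(all(abs(t_comp[j]) > abs(x[j])))
})

test_that("subcategory summaries give the stabilizing fraction", {
  labs <- rep(c("CIS_minus_trans", "TRANS_minus_cis", "CIS_plus_trans",
                "TRANS_plus_cis"), c(195, 327, 60, 135))
  s <- summarize_subcategories(labs)
  expect_identical(s$n_assignable, 717L)
  expect_equal(s$stabilizing_fraction, 522 / 717)
  expect_equal(s$stabilizing_fraction + s$destabilizing_fraction, 1)
  expect_equal(summarize_subcategories(rep("CIS_minus_trans", 5))$stabilizing_fraction, 1)
  empty <- summarize_subcategories(character(0))
  expect_true(is.na(empty$stabilizing_fraction))
})

test_that("estimated x and y track the generating effects", {
  sim <- simulate_expression(simulation_config(
    n_genes = 60, scenario_mix = c(cis = 0.5, trans = 0.5),
    measurement_sd = 0.05, seed = 41))
  eff <- estimate_effects(sim$measurements)
  joined <- dplyr::inner_join(eff, sim$truth, by = "gene_id")
  expect_equal(joined$x, joined$delta1 / log(2), tolerance = 0.15)
  expect_equal(joined$y, joined$delta0 / log(2), tolerance = 0.15)
  # with a classification attached, only cis_and_trans genes are subcategorized
  fit <- classify_dataset(sim$measurements)
  eff2 <- estimate_effects(sim$measurements, fit)
  expect_true(all(is.na(eff2$subcategory[eff2$winner != "cis_and_trans"])))
})

test_that("replicate concordance behaves on duplicated and toy samples", {
  g <- make_gene_effects(delta0 = 0.5, gene_id = "a")
  g2 <- make_gene_effects(delta0 = -0.2, a0 = 3, gene_id = "b")
  g3 <- make_gene_effects(delta0 = 1, a0 = 1, gene_id = "c")
  m <- dplyr::bind_rows(g, g2, g3)
  # duplicated sample: replicate 1 copied into replicate 2
  m$log_mean[m$replicate == 2] <- m$log_mean[m$replicate == 1]
  cc <- replicate_concordance(m, groups = c("F0_B6", "F0_CAST"))
  expect_equal(cc["F0_B6:R1", "F0_B6:R2"], 1)
  expect_equal(diag(cc), rep(1, nrow(cc)), ignore_attr = TRUE)
  expect_equal(cc, t(cc))
  # anti-correlated toy vectors
  toy <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), 2),
    group = "F0_B6", replicate = rep(1:2, each = 3),
    log_mean = log(c(1, 2, 3, 3, 2, 1)), log_sd = 0.1, polymorphic = TRUE)
  cc2 <- replicate_concordance(toy)
  expect_equal(cc2["F0_B6:R1", "F0_B6:R2"], -1)
  # independent samples decorrelate at large n
  set.seed(5)
  big <- tibble::tibble(
    gene_id = rep(sprintf("g%05d", 1:10000), 2),
    group = "F0_B6", replicate = rep(1:2, each = 10000),
    log_mean = rnorm(20000), log_sd = 0.1, polymorphic = TRUE)
  cc3 <- replicate_concordance(big)
  expect_lt(abs(cc3["F0_B6:R1", "F0_B6:R2"]), 0.05)
  # degenerate sample reported, not silently dropped
  toy2 <- toy; toy2$log_mean[toy2$replicate == 2] <- 0
  expect_warning(replicate_concordance(toy2), "zero-variance")
})

test_that("rank enrichment curves behave at the extremes and report tiers", {
  ids <- sprintf("g%02d", 1:20)
  all_known <- rank_enrichment(ids, ids)
  expect_identical(all_known$cumulative_known, 1:20)
  none_known <- rank_enrichment(ids, c("x1", "x2"))
  expect_true(all(none_known$cumulative_known == 0))
  expect_true(all(diff(all_known$cumulative_known) >= 0))
  # 29 known genes among the top 39
  ids39 <- sprintf("g%02d", 1:39)
  re <- rank_enrichment(ids39, ids39[1:29], tier_size = 39)
  expect_identical(attr(re, "tier_known"), 29L)
  expect_equal(attr(re, "tier_fraction"), 29 / 39, tolerance = 1e-12)
  expect_error(rank_enrichment(c("a", "a"), "a"), "duplicate")
})

test_that("two-tailed Fisher p matches enumeration and handles degeneracy", {
  expect_equal(fisher_exact_two_tailed(matrix(c(10, 10, 10, 10), 2)), 1)
  expect_equal(fisher_exact_two_tailed(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_true(is.na(fisher_exact_two_tailed(matrix(c(5, 3, 0, 0), 2))))
  set.seed(43)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ours <- fisher_exact_two_tailed(tab)
    expect_equal(ours, fisher_enum(tab), tolerance = 1e-12)
    expect_equal(ours, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("direction bias analysis tabulates and tests per threshold", {
  set.seed(47)
  fc <- c(rnorm(50, 1), rnorm(50, -1))
  flag <- rep(c(TRUE, FALSE), 50)
  out <- direction_bias_by_foldchange(fc, flag, thresholds = c(0, 1))
  expect_identical(nrow(out), 2L)
  expect_true(all(out$n_flagged + out$n_unflagged <= 100))
  # identical proportions in a balanced table: p = 1
  fc2 <- rep(c(1, -1), 20)
  flag2 <- rep(c(TRUE, TRUE, FALSE, FALSE), 10)
  out2 <- direction_bias_by_foldchange(fc2, flag2, thresholds = 0)
  expect_equal(out2$p_value, 1)
  # all genes in one group: degenerate margin, p absent
  out3 <- direction_bias_by_foldchange(fc2, rep(TRUE, 40), thresholds = 0)
  expect_true(is.na(out3$p_value))
  expect_error(direction_bias_by_foldchange(fc, flag, thresholds = c(1, 0.5)))
})
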