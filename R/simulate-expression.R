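SCENARIO_CLASSES <- c("conserved", "cis", "trans", "cis_and_trans",
                      "imprinted_maternal", "imprinted_paternal")

#' Configuration for the synthetic reciprocal-cross dataset
#'
#' Defines the study design emulated by [simulate_expression()]: two F0
#' homozygote classes (total expression) and two reciprocal F1 hybrid
#' crosses measured per allele, with a fixed number of biological
#' replicates per class and Gaussian measurement noise on the natural-log
#' expression scale whose standard deviation is reported alongside every
#' observation (the well-calibrated analogue of posterior summaries from a
#' probabilistic quantifier).
#'
#' @param n_genes number of genes to simulate.
#' @param replicates_per_class biological replicates per sample class
#'   (default 3, the study design).
#' @param scenario_mix named proportions over
#'   `conserved, cis, trans, cis_and_trans, imprinted_maternal,
#'   imprinted_paternal`; must sum to 1. Missing names count as 0.
#' @param effect_size_log2 magnitude of regulatory effects in log2 units
#'   (default 1, i.e. two-fold).
#' @param effect_distribution `"fixed"` (all magnitudes equal to
#'   `effect_size_log2`) or `"half_normal"` (magnitudes drawn half-normal
#'   with scale `effect_size_log2`).
#' @param measurement_sd per-observation log-e standard deviation; a single
#'   value, or a length-2 range from which each observation's sd is drawn
#'   uniformly.
#' @param baseline_log_expression_range range (log-e) from which gene
#'   baselines are drawn uniformly.
#' @param fraction_polymorphic proportion of genes with exonic
#'   polymorphisms; non-polymorphic genes yield F0 data but no
#'   allele-resolved F1 data.
#' @param sd_miscalibration_factor multiplier applied to the *reported*
#'   log_sd relative to the generating sd (1 = well-calibrated).
#' @param seed integer seed; the same config and seed reproduce the same
#'   dataset exactly.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              replicates_per_class = 3,
                              scenario_mix = c(conserved = 0.55, cis = 0.25,
                                               trans = 0.08, cis_and_trans = 0.06,
                                               imprinted_maternal = 0.03,
                                               imprinted_paternal = 0.03),
                              effect_size_log2 = 1,
                              effect_distribution = c("fixed", "half_normal"),
                              measurement_sd = 0.15,
                              baseline_log_expression_range = c(1, 6),
                              fraction_polymorphic = 1,
                              sd_miscalibration_factor = 1,
                              seed = 1L) {
  effect_distribution <- match.arg(effect_distribution)
  mix <- setNames(numeric(length(SCENARIO_CLASSES)), SCENARIO_CLASSES)
  bad <- setdiff(names(scenario_mix), SCENARIO_CLASSES)
  if (length(bad)) abort(paste0("unknown scenario class(es): ", toString(bad)))
  mix[names(scenario_mix)] <- scenario_mix
  if (any(!is.finite(mix)) || any(mix < 0)) {
    abort("scenario_mix must be finite and non-negative")
  }
  if (abs(sum(mix) - 1) > 1e-9) abort("scenario_mix must sum to 1 (within 1e-9)")
  stopifnot(is.numeric(n_genes), n_genes >= 1,
            is.numeric(replicates_per_class))
  if (replicates_per_class < 2) abort("replicates_per_class must be >= 2")
  if (!all(is.finite(measurement_sd)) || any(measurement_sd <= 0) ||
      !length(measurement_sd) %in% 1:2) {
    abort("measurement_sd must be a positive value or range")
  }
  if (!is.finite(effect_size_log2) || effect_size_log2 <= 0) {
    abort("effect_size_log2 must be positive and finite")
  }
  stopifnot(length(baseline_log_expression_range) == 2,
            all(is.finite(baseline_log_expression_range)))
  if (!is.finite(fraction_polymorphic) ||
      fraction_polymorphic < 0 || fraction_polymorphic > 1) {
    abort("fraction_polymorphic must lie in [0, 1]")
  }
  if (!is.finite(sd_miscalibration_factor) || sd_miscalibration_factor <= 0) {
    abort("sd_miscalibration_factor must be positive")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         replicates_per_class = as.integer(replicates_per_class),
         scenario_mix = mix,
         effect_size_log2 = effect_size_log2,
         effect_distribution = effect_distribution,
         measurement_sd = measurement_sd,
         baseline_log_expression_range = baseline_log_expression_range,
         fraction_polymorphic = fraction_polymorphic,
         sd_miscalibration_factor = sd_miscalibration_factor,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

draw_magnitude <- function(n, config) {
  mag_e <- config$effect_size_log2 * log(2)
  if (config$effect_distribution == "fixed") rep(mag_e, n)
  else abs(rnorm(n, 0, mag_e))
}

#' Simulate allele-specific expression with known regulatory ground truth
#'
#' Draws a gene-level truth table (regulatory class and log-e effects) and
#' emits replicate-level measurements for the six sample classes of the
#' reciprocal-cross design. Group means are
#' `F0_B6 = a0`, `F0_CAST = a0 + delta0`, and for the F1 alleles
#' `B = a1`, `C = a1 + delta1 + m` in the B6xCast cross and
#' `C = a1 + delta1 - m` in the reciprocal cross, where `m` is the signed
#' maternal-minus-paternal imprinting effect (the Cast allele is maternal
#' in the B6 male x Cast female cross). Observations add Gaussian noise of
#' sd `measurement_sd`, which is also the reported `log_sd`.
#'
#' Non-polymorphic genes cannot be measured per allele: they emit F0 rows
#' only and are flagged `polymorphic = FALSE`.
#'
#' @param config a [simulation_config()].
#' @return list with `measurements` (tibble: gene_id, group, replicate,
#'   log_mean, log_sd, polymorphic), `truth` (tibble: gene_id, class,
#'   delta0, delta1, m, polymorphic) and `config`.
#' @export
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 5, seed = 42))
#' dplyr::count(sim$measurements, group)
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("gene_%05d", seq_len(n))
  class <- sample(SCENARIO_CLASSES, n, replace = TRUE, prob = config$scenario_mix)
  polymorphic <- runif(n) < config$fraction_polymorphic
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)

  mag <- draw_magnitude(n, config)
  delta0 <- delta1 <- m <- numeric(n)
  s <- sgn(n)
  idx <- class == "cis"
  delta0[idx] <- delta1[idx] <- s[idx] * mag[idx]
  idx <- class == "trans"
  delta0[idx] <- s[idx] * mag[idx]
  idx <- class == "cis_and_trans"
  t_extra <- sgn(n) * draw_magnitude(n, config)
  delta1[idx] <- s[idx] * mag[idx]
  delta0[idx] <- delta1[idx] + t_extra[idx]
  m[class == "imprinted_maternal"] <- mag[class == "imprinted_maternal"]
  m[class == "imprinted_paternal"] <- -mag[class == "imprinted_paternal"]

  rng <- config$baseline_log_expression_range
  a0 <- runif(n, rng[1], rng[2])
  # F1 allele-level baselines are drawn independently: each allele carries
  # roughly half the diploid signal and all inference uses differences only.
  a1 <- runif(n, rng[1], rng[2]) - log(2)

  truth <- tibble::tibble(gene_id, class, delta0, delta1, m, polymorphic)

  R <- config$replicates_per_class
  grp_mean <- cbind(F0_B6 = a0,
                    F0_CAST = a0 + delta0,
                    F1i_B = a1,
                    F1i_C = a1 + delta1 + m,
                    F1r_B = a1,
                    F1r_C = a1 + delta1 - m)
  meas <- tidyr::expand_grid(gene_id = gene_id, group = ASE_GROUPS,
                             replicate = seq_len(R)) |>
    dplyr::left_join(truth[, c("gene_id", "polymorphic")], by = "gene_id") |>
    dplyr::filter(.data$polymorphic | .data$group %in% F0_GROUPS)
  mu <- grp_mean[cbind(match(meas$gene_id, gene_id), match(meas$group, ASE_GROUPS))]
  sd_gen <- if (length(config$measurement_sd) == 1L) {
    rep(config$measurement_sd, nrow(meas))
  } else {
    runif(nrow(meas), config$measurement_sd[1], config$measurement_sd[2])
  }
  meas$log_mean <- mu + rnorm(nrow(meas), 0, sd_gen)
  meas$log_sd <- sd_gen * config$sd_miscalibration_factor
  meas <- meas[, c("gene_id", "group", "replicate", "log_mean", "log_sd",
                   "polymorphic")]
  list(measurements = tibble::as_tibble(meas), truth = truth, config = config)
}
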