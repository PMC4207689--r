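imprinting_design <- function(groups, model, prior) {
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), F1_GROUPS)
  if (length(bad)) abort(paste0("imprinting models use F1 groups only, got: ",
                                toString(bad)))
  gi <- as.numeric(groups %in% c("F1i_B", "F1i_C"))
  gr <- as.numeric(groups %in% c("F1r_B", "F1r_C"))
  bsd <- prior$baseline_prior_sd
  esd <- prior$effect_prior_sd
  switch(model,
    # shared allelic difference d in both crosses
    null = list(
      X = cbind(gi, gr, d = as.numeric(groups %in% c("F1i_C", "F1r_C"))),
      prior_sd = c(bsd, bsd, esd)),
    # equal magnitude, opposite sign between the reciprocal crosses:
    # Cast-minus-B6 difference is +m in B6xCast and -m in CastxB6
    imprinting = list(
      X = cbind(gi, gr, m = (groups == "F1i_C") - (groups == "F1r_C")),
      prior_sd = c(bsd, bsd, esd)),
    abort(paste0("unknown imprinting model: ", model))
  )
}

#' Imprinting Bayes factor for one gene from reciprocal F1 hybrids
#'
#' Compares a null model, in which the Cast-minus-B6 allelic log-expression
#' difference is the same in both reciprocal crosses, against an imprinting
#' model in which the differences have equal magnitude but opposite signs.
#' Both models integrate per-cross baselines and the shared effect out
#' analytically. The Cast allele is the maternal allele in the
#' B6 male x Cast female cross, so a positive posterior imprinting effect
#' `m` (maternal minus paternal, log-e) means maternal bias.
#'
#' @param measurements tibble for a single gene containing the four F1
#'   allele series (`F1i_B`, `F1i_C`, `F1r_B`, `F1r_C`) with `log_mean`
#'   and `log_sd`.
#' @param prior a [prior_config()].
#' @param direction_threshold Bayes factor below which `direction` is
#'   reported as `"none"` (default 3, the exclusion tier).
#' @return one-row tibble: `log_bayes_factor`, `bayes_factor`,
#'   `posterior_m`, `direction` (`maternal`/`paternal`/`none`).
#' @export
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_genes = 1, scenario_mix = c(imprinted_maternal = 1), seed = 2))
#' f1 <- dplyr::filter(sim$measurements, grepl("^F1", group))
#' imprinting_bayes_factor(f1)
imprinting_bayes_factor <- function(measurements, prior = prior_config(),
                                    direction_threshold = 3) {
  missing <- check_gene_groups(measurements, F1_GROUPS)
  if (length(missing)) {
    abort(paste0("cannot compute imprinting Bayes factor; missing F1 group(s): ",
                 toString(missing)))
  }
  f1 <- measurements[measurements$group %in% F1_GROUPS, ]
  nv <- f1$log_sd^2 + prior$residual_sd^2
  d_null <- imprinting_design(f1$group, "null", prior)
  d_imp <- imprinting_design(f1$group, "imprinting", prior)
  lm_null <- gaussian_log_marginal(f1$log_mean, d_null$X, d_null$prior_sd, nv)
  lm_imp <- gaussian_log_marginal(f1$log_mean, d_imp$X, d_imp$prior_sd, nv)
  log_bf <- lm_imp - lm_null
  bf <- exp(log_bf)
  post_m <- gaussian_posterior_mean(f1$log_mean, d_imp$X, d_imp$prior_sd, nv)[3]
  direction <- if (bf < direction_threshold) "none"
               else if (post_m > 0) "maternal" else "paternal"
  tibble::tibble(log_bayes_factor = log_bf, bayes_factor = bf,
                 posterior_m = post_m, direction = direction)
}

#' Tier label for an imprinting Bayes factor
#'
#' `"extreme"` for BF >= 30 (extremely likely imprinted), `"high"` for
#' BF >= 10 (highly likely), `"possible"` for BF > 3 (excluded from the
#' cis/trans classification), otherwise `"none"`. The exclusion boundary
#' is strict: BF = 3 exactly is `"none"`.
#'
#' @param bayes_factor numeric vector of Bayes factors.
#' @return character vector of tiers.
#' @export
#' @examples
#' imprinting_tier(c(35, 12, 3.5, 3, 0.2))
imprinting_tier <- function(bayes_factor) {
  dplyr::case_when(
    bayes_factor >= 30 ~ "extreme",
    bayes_factor >= 10 ~ "high",
    bayes_factor > 3 ~ "possible",
    TRUE ~ "none"
  )
}

#' Rank all polymorphic genes by evidence of imprinting
#'
#' Runs [imprinting_bayes_factor()] on every polymorphic gene with complete
#' reciprocal F1 data, ranks genes by descending Bayes factor and attaches
#' tier labels. Genes without allele-resolved F1 data (non-polymorphic, or
#' with a missing cross) are omitted with a message.
#'
#' @param measurements measurement tibble (multiple genes) as produced by
#'   [simulate_expression()] or [read_expression_table()].
#' @inheritParams imprinting_bayes_factor
#' @return tibble of class `imprinting_scan`: `gene_id`,
#'   `log_bayes_factor`, `bayes_factor`, `posterior_m`, `direction`,
#'   `tier`, `rank` (1 = strongest evidence).
#' @export
classify_imprinting <- function(measurements, prior = prior_config(),
                                direction_threshold = 3) {
  if (nrow(measurements) == 0) abort("empty dataset")
  poly <- measurements[measurements$polymorphic %||% TRUE, ]
  complete <- poly |>
    dplyr::filter(.data$group %in% F1_GROUPS) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n_distinct(.data$group) == 4L) |>
    dplyr::ungroup()
  n_skipped <- dplyr::n_distinct(measurements$gene_id) -
    dplyr::n_distinct(complete$gene_id)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " gene(s) without complete reciprocal F1 data ",
                  "skipped in the imprinting scan"))
  }
  if (nrow(complete) == 0) abort("no gene has complete reciprocal F1 data")
  calls <- complete |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(~ imprinting_bayes_factor(.x, prior,
                                                  direction_threshold)) |>
    dplyr::ungroup() |>
    dplyr::mutate(tier = imprinting_tier(.data$bayes_factor)) |>
    dplyr::arrange(dplyr::desc(.data$log_bayes_factor)) |>
    dplyr::mutate(rank = dplyr::row_number())
  tibble::new_tibble(calls, class = "imprinting_scan")
}
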