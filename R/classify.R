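#' Posterior model probabilities and winner for a single gene
#'
#' Evaluates the four regulatory models (conserved, cis, trans,
#' cis-and-trans) on one gene's F0 and F1 measurements, converts the log
#' marginal likelihoods to posterior probabilities under an equal prior of
#' 0.25 per model (computed in log space with max subtraction), and applies
#' the confidence rules: the winning model must have posterior probability
#' above 0.5 and at least twice the posterior of the second-best model,
#' otherwise the gene is `"unclassified"` with reason `low_confidence`.
#'
#' @param measurements tibble for one gene with all six groups.
#' @param prior a [prior_config()].
#' @param imprinting_bf optional imprinting Bayes factor for the gene; if
#'   greater than 3 the gene is excluded (`imprinted_bf_gt_3`) without
#'   running the four-way comparison.
#' @return one-row tibble with log marginals (`lm_*`), posteriors
#'   (`post_*`), `winner` and `excluded_reason`.
#' @export
#' @examples
#' sim <- simulate_expression(simulation_config(
#'   n_genes = 1, scenario_mix = c(cis = 1), seed = 3))
#' classify_gene(sim$measurements)
classify_gene <- function(measurements, prior = prior_config(),
                          imprinting_bf = NULL) {
  empty <- rep(NA_real_, 4)
  skeleton <- function(winner, reason) {
    tibble::tibble(
      lm_conserved = empty[1], lm_cis = empty[2], lm_trans = empty[3],
      lm_cis_and_trans = empty[4],
      post_conserved = empty[1], post_cis = empty[2], post_trans = empty[3],
      post_cis_and_trans = empty[4],
      winner = winner, excluded_reason = reason)
  }
  if (!is.null(imprinting_bf) && !is.na(imprinting_bf) && imprinting_bf > 3) {
    return(skeleton("unclassified", "imprinted_bf_gt_3"))
  }
  if (!all(measurements$polymorphic %||% TRUE)) {
    return(skeleton("unclassified", "nonpolymorphic"))
  }
  if (length(check_gene_groups(measurements, ASE_GROUPS))) {
    return(skeleton("unclassified", "incomplete"))
  }
  lm <- vapply(ASE_MODELS, function(mod) {
    log_marginal_likelihood(measurements, mod, prior)
  }, numeric(1))
  if (all(!is.finite(lm))) abort("all four model marginals are -Inf")
  post <- exp(lm - log_sum_exp(lm))  # equal 0.25 priors cancel
  winner <- winner_from_posteriors(post)
  tibble::tibble(
    lm_conserved = lm[["conserved"]], lm_cis = lm[["cis"]],
    lm_trans = lm[["trans"]], lm_cis_and_trans = lm[["cis_and_trans"]],
    post_conserved = post[["conserved"]], post_cis = post[["cis"]],
    post_trans = post[["trans"]], post_cis_and_trans = post[["cis_and_trans"]],
    winner = winner,
    excluded_reason = if (winner == "unclassified") "low_confidence" else "none")
}

#' Apply the posterior-confidence decision rule
#'
#' The winning model must have posterior probability above 0.5 *and* at
#' least twice the posterior of the second-best model; otherwise the gene
#' is `"unclassified"`.
#'
#' @param posterior numeric vector of 4 posterior probabilities, in the
#'   order conserved, cis, trans, cis-and-trans (names optional).
#' @return the winning model label or `"unclassified"`.
#' @export
#' @examples
#' winner_from_posteriors(c(0.70, 0.20, 0.06, 0.04))  # "conserved"
#' winner_from_posteriors(c(0.55, 0.30, 0.10, 0.05))  # "unclassified"
winner_from_posteriors <- function(posterior) {
  stopifnot(length(posterior) == 4, abs(sum(posterior) - 1) < 1e-6)
  ord <- order(posterior, decreasing = TRUE)
  if (posterior[ord[1]] > 0.5 && posterior[ord[1]] >= 2 * posterior[ord[2]]) {
    ASE_MODELS[ord[1]]
  } else {
    "unclassified"
  }
}

#' Classify a whole dataset into regulatory divergence categories
#'
#' Applies the exclusion pipeline in order — non-polymorphic genes, genes
#' with imprinting Bayes factor above 3, genes with incomplete group data,
#' then the posterior-confidence rules — and classifies the remaining
#' genes as conserved, cis, trans or cis-and-trans.
#'
#' @param measurements measurement tibble covering all six groups.
#' @param prior a [prior_config()].
#' @param imprinting optional [classify_imprinting()] result; computed from
#'   `measurements` when omitted. Pass an existing scan to keep the two
#'   stages consistent in a pipeline.
#' @return object of class `ase_classification`: list with `genes` (the
#'   per-gene table including the imprinting Bayes factor), `counts` and
#'   `proportions` (over confidently classified genes), `n_confident`,
#'   `excluded` (count per exclusion reason) and `prior`. Use [tidy()] for
#'   the per-gene tibble, [glance()] for the one-row summary.
#' @export
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 40, seed = 4))
#' fit <- classify_dataset(sim$measurements)
#' glance(fit)
classify_dataset <- function(measurements, prior = prior_config(),
                             imprinting = NULL) {
  if (nrow(measurements) == 0) abort("empty dataset")
  if (is.null(imprinting)) {
    imprinting <- suppressMessages(
      tryCatch(classify_imprinting(measurements, prior),
               error = function(e) NULL))
  }
  bf_lookup <- if (is.null(imprinting)) {
    function(g) NULL
  } else {
    bfs <- setNames(imprinting$bayes_factor, imprinting$gene_id)
    function(g) unname(bfs[g])
  }
  n_failed <- 0L
  genes <- measurements |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(gm, key) {
      tryCatch(
        classify_gene(gm, prior, imprinting_bf = bf_lookup(key$gene_id)),
        error = function(e) {
          n_failed <<- n_failed + 1L
          tibble::tibble(winner = "unclassified", excluded_reason = "error")
        })
    }) |>
    dplyr::ungroup()
  if (n_failed > 0) inform(paste0(n_failed, " gene(s) failed and were skipped"))
  if (!is.null(imprinting)) {
    genes <- dplyr::left_join(
      genes,
      imprinting[, c("gene_id", "bayes_factor")] |>
        dplyr::rename(imprinting_bf = "bayes_factor"),
      by = "gene_id")
  } else {
    genes$imprinting_bf <- NA_real_
  }
  confident <- genes[genes$excluded_reason == "none", ]
  counts <- table(factor(confident$winner, levels = ASE_MODELS))
  structure(
    list(genes = genes,
         counts = as.integer(counts) |> setNames(ASE_MODELS),
         proportions = if (nrow(confident)) {
           as.numeric(counts / nrow(confident)) |> setNames(ASE_MODELS)
         } else {
           setNames(rep(NA_real_, 4), ASE_MODELS)
         },
         n_confident = nrow(confident),
         excluded = table(genes$excluded_reason[genes$excluded_reason != "none"]),
         prior = prior),
    class = "ase_classification"
  )
}

#' @export
print.ase_classification <- function(x, ...) {
  cat("Regulatory divergence classification\n")
  cat("  genes analysed:      ", nrow(x$genes), "\n")
  cat("  confidently classed: ", x$n_confident, "\n")
  for (m in ASE_MODELS) {
    cat(sprintf("    %-14s %6d (%s)\n", m, x$counts[[m]],
                ifelse(is.na(x$proportions[[m]]), "-",
                       sprintf("%.0f%%", 100 * x$proportions[[m]]))))
  }
  if (length(x$excluded)) {
    cat("  excluded:", paste(names(x$excluded), as.integer(x$excluded),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
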