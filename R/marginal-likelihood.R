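#' Prior configuration for the Gaussian model comparison
#'
#' Effects and nuisance baselines are given independent zero-mean Gaussian
#' priors on the natural-log expression scale and integrated out analytically.
#' Baseline priors must be vague relative to effect priors so that Bayes
#' factors depend on expression *differences* only, not on absolute levels.
#'
#' @param baseline_prior_sd Prior standard deviation of group baselines
#'   (log-e scale). Default 10, i.e. essentially flat over any realistic
#'   expression level.
#' @param effect_prior_sd Prior standard deviation of the cis, trans and
#'   imprinting effect parameters (log-e scale). Default 1, spanning up to
#'   several-fold allelic or strain differences.
#' @param residual_sd Extra gene-level noise added in quadrature to the
#'   reported posterior standard deviations. Default 0 (measurement
#'   variances taken at face value).
#' @return A list of class `prior_config`.
#' @export
#' @examples
#' prior_config()
#' prior_config(effect_prior_sd = 0.5)
prior_config <- function(baseline_prior_sd = 10, effect_prior_sd = 1,
                         residual_sd = 0) {
  stopifnot(is.numeric(baseline_prior_sd), is.numeric(effect_prior_sd),
            is.numeric(residual_sd))
  if (!is.finite(baseline_prior_sd) || baseline_prior_sd <= 0 ||
      !is.finite(effect_prior_sd) || effect_prior_sd <= 0 ||
      !is.finite(residual_sd) || residual_sd < 0) {
    abort("prior sds must be finite, positive (residual_sd may be 0)")
  }
  if (baseline_prior_sd < 10 * effect_prior_sd) {
    abort("baseline_prior_sd must be at least 10 * effect_prior_sd (vagueness contract)")
  }
  structure(
    list(baseline_prior_sd = baseline_prior_sd,
         effect_prior_sd = effect_prior_sd,
         residual_sd = residual_sd),
    class = "prior_config"
  )
}

#' Log marginal likelihood of a Gaussian linear model with Gaussian priors
#'
#' For observations `y ~ N(X beta, diag(noise_var))` and independent priors
#' `beta_j ~ N(0, prior_sd_j^2)`, the marginal is `y ~ N(0, X V X' + S)`
#' with `V = diag(prior_sd^2)`, `S = diag(noise_var)`; its log density at
#' `y` is returned. All model-comparison machinery in the package reduces
#' to this closed form.
#'
#' @param y numeric vector of observations (log-e expression means).
#' @param X design matrix, `length(y)` rows.
#' @param prior_sd numeric vector of per-coefficient prior sds.
#' @param noise_var numeric vector of per-observation variances.
#' @return A single number: the log marginal likelihood.
#' @export
#' @examples
#' gaussian_log_marginal(c(0.1, -0.2), cbind(1, c(0, 1)), c(10, 1), c(0.01, 0.01))
gaussian_log_marginal <- function(y, X, prior_sd, noise_var) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, ncol(X) == length(prior_sd),
            length(noise_var) %in% c(1L, n))
  if (!all(is.finite(y)) || !all(is.finite(noise_var)) || any(noise_var <= 0)) {
    abort("observations must be finite with positive variances")
  }
  if (any(!is.finite(prior_sd)) || any(prior_sd <= 0)) {
    abort("singular marginal covariance: prior sds must be finite and positive")
  }
  K <- X %*% (prior_sd^2 * t(X))
  diag(K) <- diag(K) + rep_len(noise_var, n)
  R <- tryCatch(chol(K), error = function(e) {
    abort(paste0("singular marginal covariance: ", conditionMessage(e)))
  })
  z <- backsolve(R, y, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
}

#' Posterior mean of the coefficients of the same Gaussian model
#'
#' @inheritParams gaussian_log_marginal
#' @return numeric vector of posterior means, one per column of `X`.
#' @keywords internal
#' @noRd
gaussian_posterior_mean <- function(y, X, prior_sd, noise_var) {
  X <- as.matrix(X)
  nv <- rep_len(noise_var, length(y))
  P <- crossprod(X / sqrt(nv)) + diag(1 / prior_sd^2, ncol(X))
  drop(solve(P, crossprod(X, y / nv)))
}

# Design matrix for one of the four regulatory models, given the group
# label of every observation. Baselines: F0 and F1 level each get a free
# intercept (only differences are identified by the data; absolute levels
# differ by ploidy/depth). Effects: delta0 = F0 Cast-vs-B6 strain effect,
# delta1 = F1 Cast-vs-B6 allelic effect (both crosses pooled).
ase_design <- function(groups, model, prior) {
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), ASE_GROUPS)
  if (length(bad)) abort(paste0("unknown group label(s): ", toString(bad)))
  is_f0 <- groups %in% F0_GROUPS
  b0 <- as.numeric(is_f0)
  b1 <- as.numeric(!is_f0)
  e0 <- as.numeric(groups == "F0_CAST")
  e1 <- as.numeric(groups %in% c("F1i_C", "F1r_C"))
  bsd <- prior$baseline_prior_sd
  esd <- prior$effect_prior_sd
  switch(model,
    conserved     = list(X = cbind(b0, b1),          prior_sd = c(bsd, bsd)),
    cis           = list(X = cbind(b0, b1, e0 + e1), prior_sd = c(bsd, bsd, esd)),
    trans         = list(X = cbind(b0, b1, e0),      prior_sd = c(bsd, bsd, esd)),
    cis_and_trans = list(X = cbind(b0, b1, e0, e1),  prior_sd = c(bsd, bsd, esd, esd)),
    abort(paste0("unknown model: ", model))
  )
}

check_gene_groups <- function(gene_tbl, required) {
  missing <- setdiff(required, unique(as.character(gene_tbl$group)))
  if (length(missing)) {
    return(missing)
  }
  character(0)
}

#' Log marginal likelihood of one regulatory model for one gene
#'
#' Evaluates the marginal likelihood of the gene's replicate-level
#' measurements under one of the four regulatory models. The mean structure
#' couples the F0 strain effect `delta0` and the F1 allelic effect `delta1`:
#' conserved fixes `delta0 = delta1 = 0`; cis ties `delta0 = delta1` to a
#' single free effect; trans frees `delta0` with `delta1 = 0`;
#' cis-and-trans frees both. Baselines and free effects are integrated out
#' under [prior_config()] priors.
#'
#' @param measurements tibble for a single gene with columns `group`,
#'   `log_mean`, `log_sd` (all six groups required).
#' @param model one of `"conserved"`, `"cis"`, `"trans"`, `"cis_and_trans"`.
#' @param prior a [prior_config()].
#' @return log marginal likelihood (numeric scalar).
#' @export
#' @examples
#' m <- simulate_expression(simulation_config(n_genes = 1, seed = 1))$measurements
#' log_marginal_likelihood(m, "conserved")
log_marginal_likelihood <- function(measurements, model,
                                    prior = prior_config()) {
  missing <- check_gene_groups(measurements, ASE_GROUPS)
  if (length(missing)) {
    abort(paste0("missing required group(s): ", toString(missing)))
  }
  des <- ase_design(measurements$group, model, prior)
  gaussian_log_marginal(measurements$log_mean, des$X, des$prior_sd,
                        measurements$log_sd^2 + prior$residual_sd^2)
}
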