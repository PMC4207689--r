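# Independent oracles and tiny fixture builders shared across tests.

all_groups <- c("F0_B6", "F0_CAST", "F1i_B", "F1i_C", "F1r_B", "F1r_C")
f1_groups <- c("F1i_B", "F1i_C", "F1r_B", "F1r_C")

# Build a one-gene measurement tibble from exact group means.
make_gene <- function(means, sd = 0.05, reps = 3, noise_sd = 0,
                      gene_id = "g1", polymorphic = TRUE) {
  stopifnot(!is.null(names(means)))
  tbl <- tidyr::expand_grid(gene_id = gene_id, group = names(means),
                            replicate = seq_len(reps))
  tbl$log_mean <- means[tbl$group] + rnorm(nrow(tbl), 0, noise_sd)
  tbl$log_sd <- sd
  tbl$polymorphic <- polymorphic
  tbl
}

# Six-group fixture parameterised by the effects of the generative model.
make_gene_effects <- function(delta0 = 0, delta1 = 0, m = 0, a0 = 2, a1 = 1.3,
                              ...) {
  make_gene(c(F0_B6 = a0, F0_CAST = a0 + delta0,
              F1i_B = a1, F1i_C = a1 + delta1 + m,
              F1r_B = a1, F1r_C = a1 + delta1 - m), ...)
}

# Prior-sampling Monte Carlo oracle for the Gaussian marginal likelihood:
# draws coefficients from the prior and averages the likelihood. Returns
# the log marginal and the MC standard error of the log.
mc_log_marginal <- function(y, X, prior_sd, noise_var, n_draws = 2e4) {
  X <- as.matrix(X)
  nv <- rep_len(noise_var, length(y))
  B <- matrix(rnorm(ncol(X) * n_draws, 0, prior_sd), nrow = ncol(X))
  mu <- X %*% B
  loglik <- colSums(dnorm(y, mu, sqrt(nv), log = TRUE))
  mx <- max(loglik)
  w <- exp(loglik - mx)
  logm <- mx + log(mean(w))
  se_log <- stats::sd(w) / (mean(w) * sqrt(n_draws))
  list(logm = logm, se_log = se_log)
}

# Upper-tail hypergeometric by direct choose() summation (independent of
# stats::phyper).
hyper_tail_enum <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-tailed Fisher exact by enumeration of all tables with fixed margins,
# probabilities from choose() products (independent of dhyper and of the
# implementation under test).
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(support, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }, numeric(1))
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
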