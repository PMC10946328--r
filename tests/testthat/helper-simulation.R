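# Shared fixtures: everything is generated in code at test time.

gene_spec <- function(name, family, theta) {
  list(name = name, family = family, theta = theta)
}

sim_td <- function(genes, N = 300, phi = 10, seed = 1, umi = "lognormal") {
  cfg <- simulation_config(N, genes, phi = phi, umi = umi, seed = seed)
  make_benchmark_dataset(cfg)$td
}

# Reduced-settings full fit used by unit tests (deeper runs live in the
# acceptance suite).
quick_fit <- function(td, gene, phi = 10, seed = 1, its = 1200L,
                      burn = 600L, nsub = 200L) {
  fit_gene(td, gene, phi, n_iterations = its, burn_in = burn,
    n_subsets = nsub, seed = seed)
}

# Minimal chain_ensemble with a prescribed chain, for diagnostics tests.
fake_ensemble <- function(chain, burn_in = 0L, acceptance = NULL) {
  n_iter <- dim(chain)[1]
  M <- dim(chain)[2]
  if (is.null(acceptance)) acceptance <- rep(0.5, M)
  structure(list(
    family = "uniform", gene = "fake",
    n_walkers = M, n_iterations = n_iter, burn_in = burn_in,
    chain = chain, log_post = matrix(0, n_iter, M),
    acceptance_fraction = acceptance,
    phi = 10, seed = 1L, a_stretch = 2
  ), class = "chain_ensemble")
}

# Minimal posterior_sample with given draws (matrix with named columns).
fake_posterior <- function(family, draws, gene = "g") {
  structure(list(
    family = family, gene = gene,
    draws = draws, log_post = rep(0, nrow(draws)),
    theta_mean = colMeans(draws),
    retained_walkers = 1L, acceptance_fraction = 1,
    n_iterations = nrow(draws) + 1L, burn_in = 1L, n_walkers = 2L
  ), class = "posterior_sample")
}

fake_bic_set <- function(family, values) {
  structure(list(family = family, gene = "g", values = values,
    mean = mean(values), min = min(values), max = max(values),
    n_subsets = length(values), drop_frac = 0.02),
    class = "subsample_bic")
}

# gene_fit with prescribed inflection-time samples, for cascade tests.
fake_gene_fit <- function(gene, family, times1, sign1, times2 = NULL,
                          sign2 = NULL, dynamic_class = NULL) {
  n <- length(times1)
  draws <- switch(family,
    sigmoidal = cbind(k = rep(sign1, n), L = 1, t0 = times1, bmin = 0.5),
    gaussian = cbind(a = 1, b = 0.5, t0 = (times1 + times2) / 2,
      sigma = (times2 - times1) / 2),
    double_sigmoidal = cbind(k1 = 0.5, k2 = 0.5, t1 = times1, t2 = times2,
      bmin = if (sign1 > 0) 0.5 else 2,
      bmid = if (sign1 > 0) 2 else 0.5,
      bmax = {
        mid <- if (sign1 > 0) 2 else 0.5
        if (sign2 > 0) mid + 1 else mid - 0.4
      }),
    stop("unsupported family for fake_gene_fit"))
  ps <- fake_posterior(family, draws, gene)
  fit <- gene_fit_from_posterior(ps)
  if (!is.null(dynamic_class)) fit$dynamic_class <- dynamic_class
  fit
}

# Independent NB log-pmf oracle: direct evaluation of the mean/dispersion
# pmf, with the binomial coefficient written out through log-gamma.
nb_log_pmf_direct <- function(y, mu, phi) {
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    y * log(mu / (mu + phi)) + phi * log(phi / (mu + phi))
}
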