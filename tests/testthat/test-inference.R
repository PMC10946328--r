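test_that("NB log pmf matches direct evaluation and its closed form at zero", {
  expect_equal(nb_log_pmf(0, 1, 1), log(1 / 2))
  for (mu in c(0.2, 3, 40)) {
    for (phi in c(0.5, 2, 17)) {
      expect_equal(nb_log_pmf(0, mu, phi), phi * log(phi / (mu + phi)))
    }
  }
  expect_equal(nb_log_pmf(3, 2, 5), nb_log_pmf_direct(3, 2, 5))
  expect_error(nb_log_pmf(1, 0, 1), "mu")
  expect_error(nb_log_pmf(1, 1, -1), "phi")
  # stable for very large counts
  expect_true(is.finite(nb_log_pmf(1e6, 1e5, 3)))
})

test_that("NB pmf sums to one and approaches Poisson at large dispersion", {
  for (pars in list(c(0.5, 0.7), c(2, 1), c(5, 10))) {
    mu <- pars[1]; phi <- pars[2]
    ystar <- ceiling(mu + 20 * sqrt(mu + mu^2 / phi))
    total <- sum(exp(nb_log_pmf(0:ystar, mu, phi)))
    expect_gt(total, 1 - 1e-8)
  }
  for (mu in c(0.5, 5, 50)) {
    y <- 0:200
    # convergence measured on the probability scale, where the sup-norm is
    # not dominated by the vanishing far tail
    expect_lt(max(abs(exp(nb_log_pmf(y, mu, 1e6)) - dpois(y, mu))), 1e-4)
  }
})

test_that("log likelihood maximizes near the generating level", {
  # constant-count data: 1-d grid oracle over the uniform level b
  N <- 60
  counts <- matrix(5, 1, N, dimnames = list("g", sprintf("c%02d", 1:N)))
  cm <- structure(list(gene_ids = "g", cell_ids = colnames(counts),
    counts = counts), class = "count_matrix")
  td <- build_trajectory(cm,
    data.frame(cell_id = colnames(counts), pseudotime = 1:N))
  # every cell has total 5, so M_t = M_tilde and the level maps directly
  b_truth <- lognormalize(5, 5, 5)
  grid <- seq(0.05, 4, by = 0.005)
  ll <- vapply(grid, function(b)
    log_likelihood("uniform", c(b = b), td, "g", 10), numeric(1))
  expect_lt(abs(grid[which.max(ll)] - b_truth), 0.01)
  expect_true(all(is.finite(ll)))

  # a curve pinned at (numerically) zero expression stays finite via the floor
  ll0 <- log_likelihood("uniform", c(b = 1e-300), td, "g", 10)
  expect_true(is.finite(ll0))
  expect_lt(ll0, -1000)
})

test_that("log posterior composes prior, likelihood, and the dsig gate", {
  genes <- list(gene_spec("g1", "sigmoidal",
    c(k = 0.15, L = 2, t0 = 60, bmin = 0.3)))
  td <- sim_td(genes, N = 120, seed = 5)
  ps <- prior_spec("sigmoidal", td$N, 3)
  out <- c(k = 0.1, L = 10, t0 = 60, bmin = 0.3)  # L beyond prior bound
  expect_identical(log_posterior("sigmoidal", out, td, "g1", 10, ps), -Inf)

  # flat-prior region: posterior differences equal likelihood differences
  th1 <- c(k = 0.1, L = 1.5, t0 = 50, bmin = 0.4)
  th2 <- c(k = 0.1, L = 2.5, t0 = 70, bmin = 0.2)
  dpost <- unname(log_posterior("sigmoidal", th1, td, "g1", 10, ps) -
    log_posterior("sigmoidal", th2, td, "g1", 10, ps))
  dlik <- log_likelihood("sigmoidal", th1, td, "g1", 10) -
    log_likelihood("sigmoidal", th2, td, "g1", 10)
  expect_equal(dpost, dlik)

  psd <- prior_spec("double_sigmoidal", td$N, 3)
  # tiny slope and amplitude at t1: the other transition's tail curvature
  # dominates at t1 +/- 1, so the second derivative does not change sign
  gated <- c(k1 = 0.005, k2 = 0.5, t1 = 30, t2 = 60, bmin = 0.5,
    bmid = 0.55, bmax = 2)
  expect_false(dsig_inflection_gate(gated))
  expect_identical(
    log_posterior("double_sigmoidal", gated, td, "g1", 10, psd), -Inf)
})

test_that("the ensemble sampler is deterministic and sized by family", {
  genes <- list(gene_spec("g1", "sigmoidal",
    c(k = 0.15, L = 2, t0 = 60, bmin = 0.3)))
  td <- sim_td(genes, N = 120, seed = 5)
  ce1 <- run_ensemble("sigmoidal", td, "g1", 10, n_iterations = 300,
    burn_in = 100, seed = 9)
  ce2 <- run_ensemble("sigmoidal", td, "g1", 10, n_iterations = 300,
    burn_in = 100, seed = 9)
  expect_identical(ce1$chain, ce2$chain)
  expect_identical(ce1$log_post, ce2$log_post)
  expect_identical(ce1$acceptance_fraction, ce2$acceptance_fraction)

  expect_equal(ce1$n_walkers, 16L)
  expect_equal(run_ensemble("uniform", td, "g1", 10, n_iterations = 200,
    burn_in = 50, seed = 1)$n_walkers, 4L)
  expect_equal(run_ensemble("gaussian", td, "g1", 10, n_iterations = 200,
    burn_in = 50, seed = 1)$n_walkers, 16L)
  expect_equal(run_ensemble("double_sigmoidal", td, "g1", 10,
    n_iterations = 200, burn_in = 50, seed = 1)$n_walkers, 28L)
})

test_that("uniform-level posterior concentrates on the generating level", {
  # simulation-based calibration at small scale; the central 95% interval
  # should cover the generating level in nearly all replicates
  hits <- 0L
  for (r in 1:30) {
    genes <- list(gene_spec("g", "uniform", c(b = 1.2)))
    td <- sim_td(genes, N = 200, seed = 100 + r)
    ce <- run_ensemble("uniform", td, "g", 10, n_iterations = 800,
      burn_in = 400, seed = r)
    ps <- prune_walkers(ce)
    ci <- quantile(ps$draws[, "b"], c(0.025, 0.975))
    if (ci[1] <= 1.2 && 1.2 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 27L)
})

test_that("walker pruning keeps the high-acceptance half", {
  chain <- array(rnorm(100 * 4), c(100, 4, 1), dimnames = list(NULL, NULL, "b"))
  ce <- fake_ensemble(chain, burn_in = 50L,
    acceptance = c(0.1, 0.2, 0.3, 0.4))
  ps <- prune_walkers(ce)
  expect_identical(ps$retained_walkers, c(3L, 4L))
  expect_equal(nrow(ps$draws), 2L * 50L)

  # identical traces and equal acceptance: pruning cannot move the mean
  same <- array(rep(rnorm(100), 4), c(100, 4, 1),
    dimnames = list(NULL, NULL, "b"))
  ce2 <- fake_ensemble(same, burn_in = 20L, acceptance = rep(0.3, 4))
  ps2 <- prune_walkers(ce2)
  expect_equal(unname(ps2$theta_mean["b"]), mean(same[21:100, 1, 1]))

  big <- fake_ensemble(array(rnorm(40 * 28 * 7), c(40, 28, 7),
    dimnames = list(NULL, NULL, paste0("p", 1:7))), burn_in = 10L,
    acceptance = runif(28))
  expect_length(prune_walkers(big)$retained_walkers, 14L)
})

test_that("autocorrelation diagnostics recover known chain structure", {
  set.seed(55)
  # i.i.d. chains have unit integrated autocorrelation time
  iid <- array(rnorm(5000 * 8), c(5000, 8, 1),
    dimnames = list(NULL, NULL, "b"))
  d_iid <- diagnostics(fake_ensemble(iid), T_max = 1000L)
  expect_gte(d_iid$tau[["b"]], 1)
  expect_lte(d_iid$tau[["b"]], 1.5)
  expect_equal(unname(d_iid$rho[1, "b"]), 1)

  # AR(1) with coefficient 0.9: tau = (1 + 0.9) / (1 - 0.9) = 19
  n <- 20000
  ar <- array(NA_real_, c(n, 6, 1), dimnames = list(NULL, NULL, "b"))
  for (w in 1:6) ar[, w, 1] <- as.numeric(arima.sim(list(ar = 0.9), n))
  d_ar <- diagnostics(fake_ensemble(ar), T_max = 1000L)
  expect_lt(abs(d_ar$tau[["b"]] - 19) / 19, 0.15)

  # ESS arithmetic: M * N_retained / tau
  expect_equal(d_ar$ess[["b"]], 6 * n / d_ar$tau[["b"]])
  expect_warning(diagnostics(fake_ensemble(iid[1:500, , , drop = FALSE]),
    T_max = 1000L), "T_max")
})
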