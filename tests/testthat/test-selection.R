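test_that("BIC arithmetic matches the definition", {
  # k = 1, n = 100, log-likelihood -50  ->  ln(100) + 100
  N <- 100
  counts <- matrix(rpois(N, 3) + 1, 1, N,
    dimnames = list("g", sprintf("c%03d", 1:N)))
  cm <- structure(list(gene_ids = "g", cell_ids = colnames(counts),
    counts = counts), class = "count_matrix")
  td <- build_trajectory(cm,
    data.frame(cell_id = colnames(counts), pseudotime = 1:N))

  draws <- cbind(b = rep(1.1, 10))
  ps <- fake_posterior("uniform", draws)
  got <- bic_at_mean_params(ps, td, "g", 10)
  ll <- log_likelihood("uniform", c(b = 1.1), td, "g", 10)
  expect_equal(got, 1 * log(100) - 2 * ll)

  # independent re-implementation across random draws and families
  set.seed(61)
  for (i in 1:20) {
    th <- c(k = runif(1, -0.5, 0.5), L = runif(1, 0.1, 3),
      t0 = runif(1, 1, N), bmin = runif(1, 0.1, 2))
    if (th["k"] == 0) th["k"] <- 0.1
    psig <- fake_posterior("sigmoidal", t(as.matrix(th)))
    subset <- sort(sample(N, 80))
    got <- bic_at_mean_params(psig, td, "g", 10, subset)
    f <- th[["L"]] / (1 + exp(-th[["k"]] * (subset - th[["t0"]]))) +
      th[["bmin"]]
    mu <- pmax((exp(f) - 1) * td$M[subset] / td$M_tilde, 1e-10)
    oracle <- 4 * log(80) -
      2 * sum(dnbinom(counts[1, subset], size = 10, mu = mu, log = TRUE))
    expect_equal(got, oracle)
  }
})

test_that("subsample BICs use common subsets of the right size", {
  subs <- make_subsets(100, n_subsets = 200, drop_frac = 0.02, seed = 3)
  expect_length(subs, 200L)
  expect_true(all(vapply(subs, length, 1L) == 2L))  # round(0.02 * 100)
  expect_identical(subs, make_subsets(100, 200, 0.02, seed = 3))

  N <- 100
  counts <- matrix(rpois(N, 4) + 1, 1, N,
    dimnames = list("g", sprintf("c%03d", 1:N)))
  cm <- structure(list(gene_ids = "g", cell_ids = colnames(counts),
    counts = counts), class = "count_matrix")
  td <- build_trajectory(cm,
    data.frame(cell_id = colnames(counts), pseudotime = 1:N))
  ps <- fake_posterior("uniform", cbind(b = rep(1.2, 5)))

  # degenerate subsets reproduce the full-data BIC exactly
  s0 <- subsample_bics(ps, td, "g", 10, n_subsets = 50, drop_frac = 0)
  expect_true(all(s0$values == bic_at_mean_params(ps, td, "g", 10)))

  # resampling oracle: mean subsample BIC is close to the full-data BIC
  # rescaled to the subset size
  s <- subsample_bics(ps, td, "g", 10, n_subsets = 500, drop_frac = 0.02,
    seed = 9)
  full_bic <- bic_at_mean_params(ps, td, "g", 10)
  ll_full <- (log(100) - full_bic) / 2   # = sum of per-cell log-likelihoods
  expected_mean <- log(98) - 2 * ll_full * 98 / 100
  se <- sd(s$values) / sqrt(length(s$values))
  expect_lt(abs(s$mean - expected_mean), 3 * se + 1e-9)
})

test_that("the selection cascade fires in the documented order", {
  mk <- function(fam, center, spread = 1) {
    fake_bic_set(fam, center + seq(-spread, spread, length.out = 11))
  }
  # double sigmoidal strictly dominates
  sel <- select_model(list(
    uniform = mk("uniform", 100), gaussian = mk("gaussian", 60),
    sigmoidal = mk("sigmoidal", 55), double_sigmoidal = mk("double_sigmoidal", 40)))
  expect_equal(sel$family, "double_sigmoidal")
  expect_equal(sel$branch, "dsig_dominates")

  # all non-uniform maxima overlap the uniform minimum: fall through
  sel2 <- select_model(list(
    uniform = mk("uniform", 100), gaussian = mk("gaussian", 99.5),
    sigmoidal = mk("sigmoidal", 99.7),
    double_sigmoidal = mk("double_sigmoidal", 99.9)))
  expect_equal(sel2$family, "uniform")
  expect_equal(sel2$branch, "fallthrough_uniform")

  # sigmoidal beats uniform and the gaussian mean, dsig does not dominate
  sel3 <- select_model(list(
    uniform = mk("uniform", 100), gaussian = mk("gaussian", 70),
    sigmoidal = mk("sigmoidal", 60),
    double_sigmoidal = mk("double_sigmoidal", 65)))
  expect_equal(sel3$family, "sigmoidal")

  # gaussian branch needs its mean below the sigmoidal mean
  sel4 <- select_model(list(
    uniform = mk("uniform", 100), gaussian = mk("gaussian", 60),
    sigmoidal = mk("sigmoidal", 70),
    double_sigmoidal = mk("double_sigmoidal", 65)))
  expect_equal(sel4$family, "gaussian")

  # decisions are invariant to a constant shift of all log-likelihoods
  # (BIC shifts by -2c everywhere; comparisons are unchanged)
  shift <- -2 * 37.5
  shifted <- function(s) fake_bic_set(s$family, s$values + shift)
  sel5 <- select_model(list(
    uniform = shifted(mk("uniform", 100)),
    gaussian = shifted(mk("gaussian", 70)),
    sigmoidal = shifted(mk("sigmoidal", 60)),
    double_sigmoidal = shifted(mk("double_sigmoidal", 65))))
  expect_equal(sel5$family, sel3$family)
  expect_equal(sel5$branch, sel3$branch)
})

test_that("mean parameters are repaired onto the constraint set", {
  th <- c(k1 = 0.5, k2 = 0.5, t1 = 80, t2 = 60, bmin = -0.1, bmid = 1,
    bmax = 2)
  expect_warning(rep <- repair_parameters("double_sigmoidal", th, 100),
    "projected")
  expect_lt(rep[["t1"]], rep[["t2"]])
  expect_gt(rep[["bmin"]], 0)
  ok <- c(k1 = 0.5, k2 = 0.5, t1 = 60, t2 = 80, bmin = 0.1, bmid = 1,
    bmax = 2)
  expect_identical(repair_parameters("double_sigmoidal", ok, 100), ok)
})

test_that("generating families are recovered on strong-amplitude genes", {
  genes <- list(
    gene_spec("gs", "sigmoidal", c(k = 0.1, L = 2, t0 = 150, bmin = 0.3)),
    gene_spec("gg", "gaussian", c(a = 2, b = 0.3, t0 = 150, sigma = 30)),
    gene_spec("gd", "double_sigmoidal",
      c(k1 = 0.15, k2 = 0.15, t1 = 90, t2 = 210, bmin = 2, bmid = 0.3,
        bmax = 2)),
    gene_spec("gu", "uniform", c(b = 1)))
  td <- sim_td(genes, N = 300, phi = 10, seed = 17)
  for (g in c("gs", "gg", "gd", "gu")) {
    fit <- quick_fit(td, g, seed = 4, its = 1500, burn = 750, nsub = 300)
    expected <- genes[[match(g, vapply(genes, `[[`, "", "name"))]]$family
    expect_equal(fit$selection$family, expected, label = g)
  }
})
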