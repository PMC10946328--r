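#' Negative-binomial log probability mass
#'
#' The NB pmf in mean/dispersion form,
#' \deqn{p(y \mid \mu, \phi) = \binom{y + \phi - 1}{y}
#'   \left(\frac{\mu}{\mu+\phi}\right)^{y}
#'   \left(\frac{\phi}{\mu+\phi}\right)^{\phi},}
#' with \eqn{E[Y] = \mu} and \eqn{Var[Y] = \mu + \mu^2/\phi}. Evaluated in
#' log space through log-gamma arithmetic, stable for counts up to at least
#' 1e6.
#'
#' @param y nonnegative integer count(s)
#' @param mu positive mean
#' @param phi positive dispersion
#' @return log pmf value(s), <= 0
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(phi <= 0)) stop("phi must be positive")
  if (any(y < 0)) stop("y must be nonnegative")
  stats::dnbinom(y, size = phi, mu = mu, log = TRUE)
}

# Per-cell NB log-likelihood of a curve for one gene; mu floored at a small
# epsilon since the fitted curve may map to a zero mean where the pmf is
# undefined.
loglik_cells <- function(family, theta, td, gene, phi, mu_floor = 1e-10) {
  f <- eval_model_fast(family, theta, seq_len(td$N))
  mu <- pmax(expm1(f) * td$M / td$M_tilde, mu_floor)
  stats::dnbinom(td$counts[gene, ], size = phi, mu = mu, log = TRUE)
}

#' Negative-binomial log-likelihood of a response curve
#'
#' Evaluates the fitted curve at `t = 1..N` in fit space, maps the values back
#' to count space with [inverse_lognormalize()] to obtain per-cell NB means,
#' and sums the NB log pmf over cells. Means are floored at `1e-10` so that
#' curves touching zero stay inside the pmf's domain.
#'
#' @inheritParams evaluate_model
#' @param td a `trajectory_dataset`
#' @param gene gene identifier (row of `td$counts`)
#' @param phi positive global dispersion
#' @return scalar log-likelihood
#' @export
log_likelihood <- function(family, theta, td, gene, phi) {
  family <- match.arg(family, MODEL_FAMILIES)
  bad <- check_parameters(family, theta, td$N)
  if (!is.null(bad)) {
    stop("parameter constraint violated for '", bad, "' in family ", family)
  }
  sum(loglik_cells(family, theta, td, gene, phi))
}

#' Log posterior of a response curve
#'
#' Sum of [log_prior()] and [log_likelihood()]; `-Inf` short-circuits the
#' likelihood. For the double sigmoidal family the inflection-existence gate
#' ([dsig_inflection_gate()]) must additionally pass, so every draw retained
#' by the sampler carries two well-defined inflection points.
#'
#' @inheritParams log_likelihood
#' @param ps prior specification from [prior_spec()]
#' @return scalar log posterior, possibly `-Inf`
#' @export
log_posterior <- function(family, theta, td, gene, phi, ps) {
  family <- match.arg(family, MODEL_FAMILIES)
  lp <- log_prior(family, theta, ps, td$N)
  if (!is.finite(lp)) return(-Inf)
  if (family == "double_sigmoidal" && !dsig_inflection_gate(theta)) {
    return(-Inf)
  }
  lp + sum(loglik_cells(family, theta, td, gene, phi))
}

# Batch log posterior over walker rows; used by the sampler hot loop.
# The NB log pmf is expanded as
#   lgamma(y+phi) - lgamma(phi) - lgamma(y+1) + phi log(phi)
#     + y log(mu) - (y+phi) log(mu+phi),
# whose first four terms depend only on the data and are precomputed.
make_lp_batch <- function(family, td, gene, phi, ps) {
  y <- td$counts[gene, ]
  tt <- seq_len(td$N)
  mfac <- td$M / td$M_tilde
  N <- td$N
  yphi <- y + phi
  const <- sum(lgamma(yphi) - lgamma(phi) - lfactorial(y) + phi * log(phi))
  function(theta) {
    lp <- log_prior_batch(family, theta, ps, N)
    ok <- is.finite(lp)
    if (family == "double_sigmoidal" && any(ok)) {
      gate <- dsig_gate_batch(theta[ok, , drop = FALSE])
      lp[ok][!gate] <- -Inf
      ok <- is.finite(lp)
    }
    if (any(ok)) {
      f <- eval_model_batch(family, theta[ok, , drop = FALSE], tt)
      mu <- expm1(f) * mfac
      low <- mu < 1e-10
      if (any(low)) mu[low] <- 1e-10
      ll <- drop(crossprod(log(mu), y)) -
        drop(crossprod(log(mu + phi), yphi)) + const
      lp[ok] <- lp[ok] + ll
    }
    lp
  }
}

#' Run the affine-invariant ensemble sampler for one gene and family
#'
#' Samples the log posterior with the Goodman-Weare stretch move, using the
#' two-half (red/black) update scheme: the ensemble is split in two halves and
#' each half is moved using partners drawn from the other. The stretch scale
#' is `z = ((a-1)u + 1)^2 / a` with `a = 2`, and a proposal for a
#' `d`-dimensional walker is accepted with probability
#' `min(1, z^(d-1) exp(lp_new - lp_old))`. The ensemble uses four walkers per
#' parameter and is run for `n_iterations` sweeps; the first `burn_in` sweeps
#' are later discarded by [prune_walkers()]. Acceptance fractions are tracked
#' per walker over all iterations (burn-in included) to identify stuck
#' walkers. Runs are bit-reproducible given `seed`.
#'
#' @inheritParams log_likelihood
#' @param ps prior specification; defaults to [prior_spec()] for the gene
#' @param n_iterations total number of sweeps (default 10000)
#' @param burn_in sweeps to discard before posterior summaries (default 5000)
#' @param seed integer seed controlling initialization and sampling
#' @param init optional walker start matrix; defaults to [initial_guesses()]
#' @param a_stretch stretch-move scale parameter
#' @return object of class `chain_ensemble`: list with `chain`
#'   (`n_iterations` x `M` x `d` array), `log_post` (`n_iterations` x `M`),
#'   `acceptance_fraction`, and run metadata
#' @export
run_ensemble <- function(family, td, gene, phi, ps = NULL,
                         n_iterations = 10000L, burn_in = 5000L,
                         seed = 1L, init = NULL, a_stretch = 2) {
  family <- match.arg(family, MODEL_FAMILIES)
  stopifnot(burn_in < n_iterations)
  profile <- normalized_profile(td, gene)
  if (is.null(ps)) ps <- prior_spec(family, td$N, max(profile))
  if (is.null(init)) init <- initial_guesses(family, profile, seed = seed)
  set.seed(seed + 1L)

  d <- n_parameters(family)
  M <- nrow(init)
  lp_batch <- make_lp_batch(family, td, gene, phi, ps)

  pos <- init
  lp <- lp_batch(pos)
  if (all(!is.finite(lp))) {
    stop("all walkers start at -Inf log posterior for gene '", gene,
      "', family ", family,
      "; review the priors and walker initialization")
  }

  halves <- list(seq_len(M %/% 2L), seq.int(M %/% 2L + 1L, M))
  chain <- array(NA_real_, c(n_iterations, M, d),
    dimnames = list(NULL, NULL, colnames(init)))
  log_post <- matrix(NA_real_, n_iterations, M)
  n_accept <- integer(M)

  for (it in seq_len(n_iterations)) {
    for (h in 1:2) {
      act <- halves[[h]]
      oth <- halves[[3L - h]]
      na <- length(act)
      z <- ((a_stretch - 1) * stats::runif(na) + 1)^2 / a_stretch
      partner <- oth[sample.int(length(oth), na, replace = TRUE)]
      prop <- pos[partner, , drop = FALSE] +
        z * (pos[act, , drop = FALSE] - pos[partner, , drop = FALSE])
      colnames(prop) <- colnames(init)
      lp_prop <- lp_batch(prop)
      accept <- log(stats::runif(na)) < (d - 1) * log(z) + lp_prop - lp[act]
      accept[!is.finite(lp_prop)] <- FALSE
      if (any(accept)) {
        ai <- act[accept]
        pos[ai, ] <- prop[accept, , drop = FALSE]
        lp[ai] <- lp_prop[accept]
        n_accept[ai] <- n_accept[ai] + 1L
      }
    }
    chain[it, , ] <- pos
    log_post[it, ] <- lp
  }

  structure(list(
    family = family, gene = gene,
    n_walkers = M, n_iterations = n_iterations, burn_in = burn_in,
    chain = chain, log_post = log_post,
    acceptance_fraction = n_accept / n_iterations,
    phi = phi, seed = seed, a_stretch = a_stretch
  ), class = "chain_ensemble")
}

#' Prune low-acceptance walkers and summarize the posterior
#'
#' Discards the burn-in sweeps and the half of the walkers with the lowest
#' acceptance fractions (ties broken by walker index), removing walkers that
#' were likely stuck in irrelevant local optima. No thinning is applied. The
#' mean parameter vector `<theta>` is the arithmetic mean over all retained
#' draws.
#'
#' @param ce a `chain_ensemble` from [run_ensemble()]
#' @return object of class `posterior_sample`: list with `draws`
#'   (retained draws x parameters), `log_post`, `theta_mean`,
#'   `retained_walkers`, and metadata
#' @export
prune_walkers <- function(ce) {
  stopifnot(inherits(ce, "chain_ensemble"))
  M <- ce$n_walkers
  n_keep <- as.integer(ceiling(M / 2))
  ord <- order(-ce$acceptance_fraction, seq_len(M))
  keep <- sort(ord[seq_len(n_keep)])
  iters <- seq.int(ce$burn_in + 1L, ce$n_iterations)

  sub <- ce$chain[iters, keep, , drop = FALSE]
  d <- dim(sub)[3L]
  draws <- matrix(sub, ncol = d,
    dimnames = list(NULL, dimnames(ce$chain)[[3L]]))
  lp <- as.vector(ce$log_post[iters, keep])
  structure(list(
    family = ce$family, gene = ce$gene,
    draws = draws, log_post = lp,
    theta_mean = colMeans(draws),
    retained_walkers = keep,
    acceptance_fraction = ce$acceptance_fraction[keep],
    n_iterations = ce$n_iterations, burn_in = ce$burn_in,
    n_walkers = M
  ), class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("Posterior sample: gene %s, %s fit, %d draws (%d/%d walkers)\n",
    x$gene, x$family, nrow(x$draws), length(x$retained_walkers), x$n_walkers))
  print(round(x$theta_mean, 4))
  invisible(x)
}

#' Convergence diagnostics for an ensemble run
#'
#' For each parameter the autocorrelation function is computed per walker on
#' the post-burn-in, mean-centered trace and averaged across walkers. The
#' integrated autocorrelation time is
#' \deqn{\hat\tau_f = \max_{T}\Big(1 + 2 \sum_{\tau=1}^{T}
#'   \langle\rho_f(\tau)\rangle\Big),}
#' and the effective sample size is \eqn{ESS = M N_{ret} / \hat\tau_f} with
#' `M` walkers and `N_ret` post-burn-in sweeps.
#'
#' @param ce a `chain_ensemble`
#' @param T_max largest time delay considered (reduced with a warning when the
#'   post-burn-in chain is shorter)
#' @return object of class `diagnostics_report`: list with per-parameter
#'   `rho` (matrix, delays x parameters), `tau`, `ess`, and the per-walker
#'   acceptance fractions
#' @export
diagnostics <- function(ce, T_max = 1000L) {
  stopifnot(inherits(ce, "chain_ensemble"))
  iters <- seq.int(ce$burn_in + 1L, ce$n_iterations)
  len <- length(iters)
  if (len <= T_max) {
    warning("post-burn-in chain length (", len, ") <= T_max; reducing T_max")
    T_max <- len - 1L
  }
  pn <- dimnames(ce$chain)[[3L]]
  M <- ce$n_walkers
  rho <- matrix(0, T_max + 1L, length(pn),
    dimnames = list(NULL, pn))
  for (j in seq_along(pn)) {
    acc <- numeric(T_max + 1L)
    for (w in seq_len(M)) {
      x <- ce$chain[iters, w, j]
      if (stats::sd(x) == 0) {
        # a walker that never moved is perfectly autocorrelated
        acc <- acc + 1
      } else {
        acc <- acc + drop(stats::acf(x, lag.max = T_max, plot = FALSE,
          demean = TRUE)$acf)
      }
    }
    rho[, j] <- acc / M
  }
  # tau_hat = max over T in [0, T_max] of 1 + 2 * sum_{tau<=T} <rho(tau)>
  tau <- apply(rho, 2L, function(r) max(1 + 2 * cumsum(c(0, r[-1L]))))
  ess <- M * len / tau
  structure(list(
    rho = rho, tau = tau, ess = ess,
    acceptance_fraction = ce$acceptance_fraction,
    n_retained = len, n_walkers = M, T_max = T_max
  ), class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("MCMC diagnostics\n")
  print(data.frame(tau = round(x$tau, 2), ess = round(x$ess, 1)))
  cat(sprintf("  acceptance fractions: %s\n",
    paste(round(x$acceptance_fraction, 3), collapse = " ")))
  invisible(x)
}
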