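#' Repair a mean parameter vector onto the constraint set
#'
#' The posterior-mean parameters `<theta>` can violate hard constraints when
#' the posterior is multimodal (e.g. the means of `t1` and `t2` crossing).
#' Since the model-selection procedure needs a BIC for every family, the mean
#' is projected back onto the constraint set: inverted `t1 > t2` pairs are
#' swapped (with a minimal separation when equal), positivity constraints are
#' clamped at a small epsilon, and location parameters are clamped to
#' `[1, N]`. A warning is emitted whenever a repair was needed.
#'
#' @inheritParams evaluate_model
#' @return repaired named parameter vector
#' @export
repair_parameters <- function(family, theta, N) {
  family <- match.arg(family, MODEL_FAMILIES)
  orig <- theta
  eps <- 1e-6
  clamp_pos <- function(nm) {
    if (nm %in% names(theta) && theta[[nm]] <= 0) theta[[nm]] <<- eps
  }
  clamp_loc <- function(nm) {
    if (nm %in% names(theta)) {
      theta[[nm]] <<- min(max(theta[[nm]], 1), N)
    }
  }
  for (nm in c("b", "a", "sigma", "L", "bmin", "bmid", "bmax", "k1", "k2")) {
    clamp_pos(nm)
  }
  if (family == "sigmoidal" && theta[["k"]] == 0) theta[["k"]] <- eps
  for (nm in c("t0", "t1", "t2")) clamp_loc(nm)
  if (family == "double_sigmoidal" && theta[["t1"]] >= theta[["t2"]]) {
    tmp <- sort(c(theta[["t1"]], theta[["t2"]]))
    if (diff(tmp) < eps) tmp <- tmp + c(-eps, eps)
    theta[["t1"]] <- max(tmp[1], 1)
    theta[["t2"]] <- min(tmp[2], N)
  }
  if (!isTRUE(all.equal(orig, theta))) {
    warning("mean parameters violated constraints for family ", family,
      "; projected onto the constraint set")
  }
  theta
}

#' BIC of a family at its posterior-mean parameters
#'
#' The Bayesian information criterion \eqn{k \ln(n) - 2 \ln \hat L} with the
#' maximized likelihood replaced by the likelihood at the posterior mean
#' `<theta>`, evaluated on a subset of cells: `k` is the family's parameter
#' count and `n` the subset size.
#'
#' @param ps a `posterior_sample`
#' @param td a `trajectory_dataset`
#' @param gene gene identifier
#' @param phi global dispersion
#' @param subset integer vector of cell positions (pseudotime ranks) to score;
#'   defaults to all cells
#' @return scalar BIC value
#' @export
bic_at_mean_params <- function(ps, td, gene, phi, subset = seq_len(td$N)) {
  stopifnot(inherits(ps, "posterior_sample"))
  theta <- repair_parameters(ps$family, ps$theta_mean, td$N)
  ll <- loglik_cells(ps$family, theta, td, gene, phi)
  n_parameters(ps$family) * log(length(subset)) - 2 * sum(ll[subset])
}

#' Random cell subsets shared across model families
#'
#' Draws `n_subsets` index sets, each dropping `round(drop_frac * N)` cells
#' without replacement, independently per subset. The same subset sequence is
#' reused for all four families so that BIC comparisons share their
#' Monte-Carlo noise.
#'
#' @param N number of cells
#' @param n_subsets number of subsets
#' @param drop_frac fraction of cells removed per subset
#' @param seed integer seed
#' @return list of integer vectors of dropped cell positions (possibly empty)
#' @export
make_subsets <- function(N, n_subsets = 10000L, drop_frac = 0.02, seed = 1L) {
  set.seed(seed)
  n_drop <- round(drop_frac * N)
  lapply(seq_len(n_subsets), function(i) {
    if (n_drop == 0L) integer() else sample.int(N, n_drop)
  })
}

#' Subsample BIC distribution for one fitted family
#'
#' A cross-validation-flavoured stabilization of the BIC: the model is fit
#' once on the full data (through the MCMC), and its BIC at the posterior-mean
#' parameters is then evaluated on many random 98% subsets of the cells. The
#' per-cell log-likelihood at `<theta>` is computed once, so each subset costs
#' only a subtraction of the dropped cells' terms.
#'
#' @inheritParams bic_at_mean_params
#' @param n_subsets number of subsets (default 10000)
#' @param drop_frac fraction of cells dropped per subset (default 0.02)
#' @param seed seed for the subset sequence (ignored when `subsets` given)
#' @param subsets optional precomputed subset list from [make_subsets()],
#'   shared across families
#' @return object of class `subsample_bic`: list with `family`, `values`
#'   (numeric vector of BICs), and `mean`/`min`/`max` summaries
#' @export
subsample_bics <- function(ps, td, gene, phi, n_subsets = 10000L,
                           drop_frac = 0.02, seed = 1L, subsets = NULL) {
  stopifnot(inherits(ps, "posterior_sample"))
  if (is.null(subsets)) subsets <- make_subsets(td$N, n_subsets, drop_frac, seed)
  theta <- repair_parameters(ps$family, ps$theta_mean, td$N)
  ll <- loglik_cells(ps$family, theta, td, gene, phi)
  full <- sum(ll)
  k <- n_parameters(ps$family)
  vals <- vapply(subsets, function(drop) {
    n_sub <- td$N - length(drop)
    k * log(n_sub) - 2 * (full - sum(ll[drop]))
  }, numeric(1))
  structure(list(
    family = ps$family, gene = gene, values = vals,
    mean = mean(vals), min = min(vals), max = max(vals),
    n_subsets = length(subsets), drop_frac = drop_frac
  ), class = "subsample_bic")
}

#' Select the best-fitting family from subsample BIC sets
#'
#' Implements the fixed decision cascade over the four families' subsample
#' BIC distributions (all computed on the same subset sequence):
#' \enumerate{
#'   \item double sigmoidal, if `max(BIC_dsig) < min(BIC_unif)` and its mean
#'     BIC beats both the Gaussian and sigmoidal means;
#'   \item else sigmoidal, if `max(BIC_sig) < min(BIC_unif)` and its mean
#'     beats the Gaussian mean;
#'   \item else Gaussian, if `max(BIC_gauss) < min(BIC_unif)` and its mean
#'     beats the sigmoidal mean;
#'   \item else uniform.
#' }
#' Requiring the non-uniform family's worst subset BIC to beat the uniform
#' family's best makes the non-uniform call robust to outlier cells, and the
#' branch order prefers simpler families when fits are comparable.
#'
#' @param sets named list of `subsample_bic` objects, one per family (names
#'   `uniform`, `gaussian`, `sigmoidal`, `double_sigmoidal`)
#' @return object of class `model_selection`: list with `family` (the
#'   chosen one), `branch` (which rule fired), and the per-family summaries
#' @export
select_model <- function(sets) {
  stopifnot(all(MODEL_FAMILIES %in% names(sets)))
  mx <- vapply(sets, function(s) s$max, numeric(1))
  mn <- vapply(sets, function(s) s$min, numeric(1))
  mea <- vapply(sets, function(s) s$mean, numeric(1))

  if (mx[["double_sigmoidal"]] < mn[["uniform"]] &&
      mea[["double_sigmoidal"]] < mea[["gaussian"]] &&
      mea[["double_sigmoidal"]] < mea[["sigmoidal"]]) {
    family <- "double_sigmoidal"; branch <- "dsig_dominates"
  } else if (mx[["sigmoidal"]] < mn[["uniform"]] &&
             mea[["sigmoidal"]] < mea[["gaussian"]]) {
    family <- "sigmoidal"; branch <- "sig_dominates"
  } else if (mx[["gaussian"]] < mn[["uniform"]] &&
             mea[["gaussian"]] < mea[["sigmoidal"]]) {
    family <- "gaussian"; branch <- "gauss_dominates"
  } else {
    family <- "uniform"; branch <- "fallthrough_uniform"
  }
  summaries <- data.frame(
    family = MODEL_FAMILIES,
    bic_mean = mea[MODEL_FAMILIES],
    bic_min = mn[MODEL_FAMILIES],
    bic_max = mx[MODEL_FAMILIES],
    row.names = NULL
  )
  structure(list(family = family, branch = branch, summaries = summaries),
    class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection:", x$family, sprintf("(branch: %s)\n", x$branch))
  print(x$summaries, digits = 6)
  invisible(x)
}
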