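#' Model families for pseudotime response curves
#'
#' Four parametric families describe gene expression along a pseudotime
#' trajectory in log-normalized (fit) space: a uniform level (no dynamics), a
#' Gaussian impulse, a sigmoidal state switch, and a double sigmoidal capturing
#' impulses with asymmetric rise/fall rates as well as stepwise two-level
#' transitions.
#'
#' Parameter vectors are plain named numeric vectors:
#' \itemize{
#'   \item uniform: \code{b}
#'   \item gaussian: \code{a, b, t0, sigma} giving
#'     \eqn{a e^{-(t-t_0)^2/(2\sigma^2)} + b}
#'   \item sigmoidal: \code{k, L, t0, bmin} giving
#'     \eqn{L/(1+e^{-k(t-t_0)}) + b_{min}}
#'   \item double_sigmoidal: \code{k1, k2, t1, t2, bmin, bmid, bmax} giving
#'     \eqn{b_{min} + (b_{mid}-b_{min})/(1+e^{-k_1(t-t_1)}) +
#'          (b_{max}-b_{mid})/(1+e^{-k_2(t-t_2)})}
#' }
#'
#' @name model-families
#' @keywords internal
NULL

MODEL_FAMILIES <- c("uniform", "gaussian", "sigmoidal", "double_sigmoidal")

#' Parameter names of a model family
#'
#' @param family one of `"uniform"`, `"gaussian"`, `"sigmoidal"`,
#'   `"double_sigmoidal"`
#' @return character vector of parameter names, in canonical order
#' @export
model_parameters <- function(family) {
  switch(match.arg(family, MODEL_FAMILIES),
    uniform          = "b",
    gaussian         = c("a", "b", "t0", "sigma"),
    sigmoidal        = c("k", "L", "t0", "bmin"),
    double_sigmoidal = c("k1", "k2", "t1", "t2", "bmin", "bmid", "bmax")
  )
}

#' Number of free parameters of a family
#' @inheritParams model_parameters
#' @export
n_parameters <- function(family) length(model_parameters(family))

#' Ensemble size used for a family
#'
#' The ensemble sampler uses four walkers per parameter: 4 for the uniform
#' fit, 16 for the Gaussian and sigmoidal fits, 28 for the double sigmoidal.
#'
#' @inheritParams model_parameters
#' @export
n_walkers <- function(family) 4L * n_parameters(family)

# Returns NULL when theta satisfies the family's hard constraints, otherwise
# the name of the first violated parameter. Pseudotime bounds are checked only
# when N is finite.
check_parameters <- function(family, theta, N = Inf) {
  family <- match.arg(family, MODEL_FAMILIES)
  p <- function(name) unname(theta[[name]])
  switch(family,
    uniform = {
      if (!isTRUE(p("b") > 0)) return("b")
      NULL
    },
    gaussian = {
      if (!isTRUE(p("a") > 0)) return("a")
      if (!isTRUE(p("b") > 0)) return("b")
      if (!isTRUE(p("sigma") > 0)) return("sigma")
      if (!isTRUE(p("t0") >= 1 && p("t0") <= N)) return("t0")
      NULL
    },
    sigmoidal = {
      if (!isTRUE(p("k") != 0)) return("k")
      if (!isTRUE(p("L") > 0)) return("L")
      if (!isTRUE(p("bmin") > 0)) return("bmin")
      if (!isTRUE(p("t0") >= 1 && p("t0") <= N)) return("t0")
      NULL
    },
    double_sigmoidal = {
      for (nm in c("bmin", "bmid", "bmax", "k1", "k2")) {
        if (!isTRUE(p(nm) > 0)) return(nm)
      }
      if (!isTRUE(p("t1") >= 1)) return("t1")
      if (!isTRUE(p("t1") < p("t2"))) return("t2")
      if (!isTRUE(p("t2") <= N)) return("t2")
      NULL
    }
  )
}

# Fast, unchecked, vectorized-in-t evaluation.
eval_model_fast <- function(family, theta, t) {
  switch(family,
    uniform = rep.int(theta[[1L]], length(t)),
    gaussian = {
      theta[["a"]] * exp(-(t - theta[["t0"]])^2 / (2 * theta[["sigma"]]^2)) +
        theta[["b"]]
    },
    sigmoidal = {
      theta[["L"]] / (1 + exp(-theta[["k"]] * (t - theta[["t0"]]))) +
        theta[["bmin"]]
    },
    double_sigmoidal = {
      theta[["bmin"]] +
        (theta[["bmid"]] - theta[["bmin"]]) /
          (1 + exp(-theta[["k1"]] * (t - theta[["t1"]]))) +
        (theta[["bmax"]] - theta[["bmid"]]) /
          (1 + exp(-theta[["k2"]] * (t - theta[["t2"]])))
    }
  )
}

#' Evaluate a response function
#'
#' Evaluates the family's response curve at pseudotime positions `t` in
#' log-normalized (fit) space, after validating the family's parameter
#' constraints.
#'
#' @inheritParams model_parameters
#' @param theta named numeric parameter vector (see [model_parameters()])
#' @param t numeric vector of pseudotime positions
#' @param N number of cells in the trajectory; when supplied, location
#'   parameters are required to lie in `[1, N]`
#' @return numeric vector of function values, same length as `t`
#' @export
#' @examples
#' evaluate_model("sigmoidal", c(k = 0.1, L = 2, t0 = 50, bmin = 0.5), t = 50)
evaluate_model <- function(family, theta, t, N = Inf) {
  family <- match.arg(family, MODEL_FAMILIES)
  pn <- model_parameters(family)
  if (!all(pn %in% names(theta))) {
    stop("missing parameter(s): ", paste(setdiff(pn, names(theta)), collapse = ", "))
  }
  bad <- check_parameters(family, theta, N)
  if (!is.null(bad)) {
    stop("parameter constraint violated for '", bad, "' in family ", family)
  }
  eval_model_fast(family, theta, t)
}

# N x m matrix of curve values for m walkers (rows of theta).
eval_model_batch <- function(family, theta, t) {
  m <- nrow(theta)
  out <- matrix(0, length(t), m)
  for (i in seq_len(m)) out[, i] <- eval_model_fast(family, theta[i, ], t)
  out
}

#' Folded-normal density
#'
#' Density of \eqn{|X|} for \eqn{X \sim N(\mu, \sigma^2)}:
#' \deqn{p(x) = \frac{1}{\sqrt{2\pi\sigma^2}} e^{-(x-\mu)^2/(2\sigma^2)} +
#'              \frac{1}{\sqrt{2\pi\sigma^2}} e^{-(x+\mu)^2/(2\sigma^2)},
#'   \quad x \ge 0.}
#' With \eqn{\mu = 0} this is twice the centered normal density; it is used as
#' a shrinkage prior on slope and width parameters.
#'
#' @param x quantiles (density is 0 for `x < 0`)
#' @param mu location of the underlying normal
#' @param sigma standard deviation of the underlying normal
#' @param log return log density?
#' @export
dfoldnorm <- function(x, mu = 0, sigma = 1, log = FALSE) {
  # log-space addition of the two reflected normal terms avoids underflow
  d1 <- stats::dnorm(x, mu, sigma, log = TRUE)
  d2 <- stats::dnorm(-x, mu, sigma, log = TRUE)
  hi <- pmax(d1, d2)
  ld <- hi + log1p(exp(pmin(d1, d2) - hi))
  ld[x < 0] <- -Inf
  if (log) ld else exp(ld)
}

#' Prior specification for a model family
#'
#' Level parameters (`b`, `a`, `L`, `bmin`, `bmid`, `bmax`) get uninformative
#' uniform priors on `(0.01, 2 * max ytilde)`, keeping fitted levels within an
#' interpretable range of the data. Location parameters (`t0`, `t1`, `t2`)
#' are uniform on `[1, N]`. Slope parameters (`k`, `k1`, `k2`) get a
#' folded-normal prior with mean 0 and variance 0.1, shrinking towards gentle
#' transitions (curve shape is nearly invariant once the slope is large). The
#' Gaussian width `sigma` gets a folded-normal prior with mean 0 and variance
#' `N / 10`, discouraging degenerate flat fits. For the sigmoidal family the
#' slope prior is applied to `|k|`, leaving the sign (direction of the state
#' switch) free.
#'
#' @inheritParams model_parameters
#' @param N number of cells in the trajectory
#' @param y_max maximum log-normalized expression of the gene being fit
#' @return named list, one entry per parameter, each a list with `type`
#'   (`"uniform"` or `"folded_normal"`) and its hyperparameters
#' @export
prior_spec <- function(family, N, y_max) {
  family <- match.arg(family, MODEL_FAMILIES)
  level <- list(type = "uniform", lo = 0.01, hi = max(2 * y_max, 0.02))
  loc <- list(type = "uniform", lo = 1, hi = N)
  slope <- list(type = "folded_normal", var = 0.1)
  switch(family,
    uniform = list(b = level),
    gaussian = list(a = level, b = level, t0 = loc,
      sigma = list(type = "folded_normal", var = N / 10)),
    sigmoidal = list(k = slope, L = level, t0 = loc, bmin = level),
    double_sigmoidal = list(k1 = slope, k2 = slope, t1 = loc, t2 = loc,
      bmin = level, bmid = level, bmax = level)
  )
}

# Nominal width of each prior, used to scale walker initialization jitter.
prior_range <- function(ps) {
  vapply(ps, function(p) {
    if (p$type == "uniform") p$hi - p$lo else 3 * sqrt(p$var)
  }, numeric(1))
}

#' Log prior density of a parameter vector
#'
#' Sum of per-parameter log densities under [prior_spec()]-style priors, with
#' `-Inf` signalling a violated hard constraint or uniform bound. Slope priors
#' are evaluated at the absolute slope.
#'
#' @inheritParams evaluate_model
#' @param ps prior specification from [prior_spec()]
#' @return scalar log density, possibly `-Inf`
#' @export
log_prior <- function(family, theta, ps, N = Inf) {
  th <- matrix(theta, nrow = 1, dimnames = list(NULL, names(theta)))
  unname(log_prior_batch(family, th, ps, N))
}

# Vectorized over walkers (rows of theta). Column order must match
# model_parameters(family).
log_prior_batch <- function(family, theta, ps, N) {
  m <- nrow(theta)
  lp <- numeric(m)
  ok <- switch(family,
    uniform = theta[, 1L] > 0,
    gaussian = theta[, 1L] > 0 & theta[, 2L] > 0 & theta[, 4L] > 0 &
      theta[, 3L] >= 1 & theta[, 3L] <= N,
    sigmoidal = theta[, 1L] != 0 & theta[, 2L] > 0 & theta[, 4L] > 0 &
      theta[, 3L] >= 1 & theta[, 3L] <= N,
    double_sigmoidal = theta[, 1L] > 0 & theta[, 2L] > 0 &
      theta[, 3L] >= 1 & theta[, 3L] < theta[, 4L] & theta[, 4L] <= N &
      theta[, 5L] > 0 & theta[, 6L] > 0 & theta[, 7L] > 0
  )
  lp[!ok] <- -Inf
  for (j in seq_along(ps)) {
    p <- ps[[j]]
    x <- theta[, j]
    if (p$type == "uniform") {
      inside <- x >= p$lo & x <= p$hi
      lp[!inside] <- -Inf
      lp[ok & inside] <- lp[ok & inside] - log(p$hi - p$lo)
    } else {
      lp <- lp + dfoldnorm(abs(x), 0, sqrt(p$var), log = TRUE)
    }
  }
  lp
}

#' Initial walker positions for the ensemble sampler
#'
#' Gaussian and sigmoidal walkers start from a nonlinear least-squares fit of
#' the family to the log-normalized profile, perturbed per walker with additive
#' Gaussian noise (scale: 1% of each parameter's prior range); if the
#' least-squares fit fails a moment-based heuristic start is used instead.
#' Double sigmoidal walkers are drawn to cover the qualitatively distinct
#' shapes the family can take (step-up, step-down, impulse-up, impulse-down)
#' with randomized locations `t1 < t2`, and are rejection-sampled until the
#' inflection-existence gate ([dsig_inflection_gate()]) passes. Uniform walkers
#' are drawn uniformly between 0.01 and the maximum expression level.
#'
#' @inheritParams model_parameters
#' @param profile numeric vector of log-normalized expression, ordered by
#'   pseudotime rank `t = 1..N`
#' @param n_walkers number of walkers; defaults to four per parameter
#' @param seed integer seed; the result is deterministic given the seed
#' @return matrix (`n_walkers` x `n_parameters`) of valid parameter vectors
#' @export
initial_guesses <- function(family, profile,
                            n_walkers = 4L * n_parameters(family),
                            seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  set.seed(seed)
  N <- length(profile)
  y_max <- max(profile)
  ps <- prior_spec(family, N, y_max)
  pn <- model_parameters(family)
  out <- matrix(NA_real_, n_walkers, length(pn), dimnames = list(NULL, pn))

  if (family == "uniform") {
    hi <- max(y_max, 0.02)
    out[, "b"] <- stats::runif(n_walkers, 0.01, hi)
    return(out)
  }

  if (family == "double_sigmoidal") {
    lo_lvl <- max(0.05, stats::quantile(profile, 0.25))
    hi_lvl <- max(y_max, lo_lvl + 0.5)
    mid_lvl <- (lo_lvl + hi_lvl) / 2
    shapes <- list(
      impulse_up   = c(lo_lvl, hi_lvl, lo_lvl),
      impulse_down = c(hi_lvl, lo_lvl, hi_lvl),
      step_up      = c(lo_lvl, mid_lvl, hi_lvl),
      step_down    = c(hi_lvl, mid_lvl, lo_lvl)
    )
    for (i in seq_len(n_walkers)) {
      lv <- shapes[[((i - 1L) %% 4L) + 1L]]
      for (try in 1:200) {
        t1 <- stats::runif(1, 1 + 0.05 * N, 0.45 * N)
        t2 <- stats::runif(1, 0.55 * N, 0.95 * N)
        th <- c(k1 = abs(stats::rnorm(1, 0, 0.3)) + 0.05,
                k2 = abs(stats::rnorm(1, 0, 0.3)) + 0.05,
                t1 = t1, t2 = t2,
                bmin = lv[1] * exp(stats::rnorm(1, 0, 0.1)),
                bmid = lv[2] * exp(stats::rnorm(1, 0, 0.1)),
                bmax = lv[3] * exp(stats::rnorm(1, 0, 0.1)))
        if (is.null(check_parameters(family, th, N)) &&
            dsig_inflection_gate(th) &&
            is.finite(log_prior(family, th, ps, N))) break
      }
      out[i, ] <- th
    }
    return(out)
  }

  # gaussian / sigmoidal: least-squares point fit, then per-walker jitter
  fit <- point_fit(family, profile)
  jitter_sd <- 0.01 * prior_range(ps)
  for (i in seq_len(n_walkers)) {
    for (try in 1:200) {
      th <- fit + stats::rnorm(length(fit), 0, jitter_sd)
      names(th) <- pn
      th <- clamp_to_support(family, th, ps, N)
      if (is.null(check_parameters(family, th, N)) &&
          is.finite(log_prior(family, th, ps, N))) break
    }
    out[i, ] <- th
  }
  out
}

# Least-squares point estimate for the gaussian/sigmoidal families. The
# nonlinear shape parameters are scanned on a coarse grid; at each grid node
# the level parameters enter linearly and are solved in closed form, which
# avoids the step-function local minima a single descent run can fall into.
# The best grid node is then refined by Nelder-Mead; on failure the grid
# winner itself is the (moment-based) fallback.
point_fit <- function(family, profile) {
  N <- length(profile)
  tt <- seq_len(N)
  t0_grid <- seq(0.1 * N, 0.9 * N, length.out = 9)

  lin_ls <- function(basis) {
    # fit profile ~ c0 + c1 * basis
    fit <- stats::lm.fit(cbind(1, basis), profile)
    unname(fit$coefficients)
  }
  cand_sse <- function(cand) {
    sum((profile - eval_model_fast(family, cand, tt))^2)
  }

  best <- NULL
  take <- function(cand) {
    sse <- cand_sse(cand)
    if (is.null(best) || sse < best$sse) best <<- list(par = cand, sse = sse)
  }
  if (family == "gaussian") {
    for (t0 in t0_grid) {
      for (sg in N * c(0.03, 0.06, 0.1, 0.2, 0.35)) {
        co <- lin_ls(exp(-(tt - t0)^2 / (2 * sg^2)))
        take(c(a = max(co[2], 0.05), b = max(co[1], 0.02), t0 = t0,
          sigma = sg))
      }
    }
  } else {
    for (t0 in t0_grid) {
      for (k in c(0.02, 0.05, 0.1, 0.25, 0.6)) {
        co <- lin_ls(1 / (1 + exp(-k * (tt - t0))))
        if (co[2] >= 0) {
          take(c(k = k, L = max(co[2], 0.05), t0 = t0,
            bmin = max(co[1], 0.02)))
        } else {
          # negative amplitude is the mirrored decreasing sigmoid:
          # b + L s_k(t) = (b + L) + (-L) s_{-k}(t)
          take(c(k = -k, L = -co[2], t0 = t0,
            bmin = max(co[1] + co[2], 0.02)))
        }
      }
    }
  }
  start <- best$par

  obj <- function(par) {
    names(par) <- names(start)
    if (family == "gaussian" && (par["a"] <= 0 || par["sigma"] <= 0)) {
      return(1e10)
    }
    if (family == "sigmoidal" && par["L"] <= 0) return(1e10)
    sum((profile - eval_model_fast(family, par, tt))^2)
  }
  fit <- tryCatch(
    stats::optim(start, obj, method = "Nelder-Mead",
      control = list(maxit = 2000))$par,
    error = function(e) {
      message("least-squares refinement failed (", conditionMessage(e),
        "); using grid start")
      start
    })
  names(fit) <- names(start)
  fit
}

# Push a jittered vector back inside the prior support.
clamp_to_support <- function(family, th, ps, N) {
  eps <- 1e-6
  for (nm in names(ps)) {
    p <- ps[[nm]]
    if (p$type == "uniform") {
      th[nm] <- min(max(th[nm], p$lo + eps), p$hi - eps)
    }
  }
  if (family == "gaussian") th["sigma"] <- max(abs(th["sigma"]), eps)
  if (family == "sigmoidal") {
    # a runaway least-squares slope is indistinguishable from a step; start
    # walkers at a moderate slope where the shrinkage prior has mass
    if (th["k"] == 0) th["k"] <- eps
    th["k"] <- sign(th["k"]) * min(abs(th["k"]), 2)
  }
  th
}
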