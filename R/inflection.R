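#' Closed-form second derivative of a response function
#'
#' Inflection points are where the curvature of the fitted response changes
#' sign. The non-uniform families admit closed forms:
#' \deqn{f''_{gauss}(t) = \frac{a}{\sigma^4} e^{-(t-t_0)^2/(2\sigma^2)}
#'   (t-(t_0-\sigma))(t-(t_0+\sigma))}
#' \deqn{f''_{sig}(t) = \frac{k^2 L\, e^{-k(t-t_0)}(e^{-k(t-t_0)}-1)}
#'   {(1+e^{-k(t-t_0)})^3}}
#' and for the double sigmoidal the sum of two such terms with amplitudes
#' \eqn{b_{mid}-b_{min}} and \eqn{b_{max}-b_{mid}}.
#'
#' @inheritParams evaluate_model
#' @return numeric vector of second-derivative values
#' @export
second_derivative <- function(family, theta, t) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (family == "uniform") {
    stop("the uniform family has no curvature; no inflection points exist")
  }
  switch(family,
    gaussian = {
      a <- theta[["a"]]; t0 <- theta[["t0"]]; s <- theta[["sigma"]]
      a / s^4 * exp(-(t - t0)^2 / (2 * s^2)) * (t - (t0 - s)) * (t - (t0 + s))
    },
    sigmoidal = {
      sig_d2_term(theta[["k"]], theta[["L"]], theta[["t0"]], t)
    },
    double_sigmoidal = {
      sig_d2_term(theta[["k1"]], theta[["bmid"]] - theta[["bmin"]],
        theta[["t1"]], t) +
        sig_d2_term(theta[["k2"]], theta[["bmax"]] - theta[["bmid"]],
          theta[["t2"]], t)
    }
  )
}

# k^2 L e^{-k(t-t0)} (e^{-k(t-t0)} - 1) / (1 + e^{-k(t-t0)})^3
sig_d2_term <- function(k, L, t0, t) {
  e <- exp(-k * (t - t0))
  k^2 * L * e * (e - 1) / (1 + e)^3
}

#' Inflection-existence gate for the double sigmoidal family
#'
#' The double sigmoidal can have a varying number of inflection points; its
#' two transitions are anchored at `t1` and `t2` only when the second
#' derivative genuinely changes sign in a window around each. A parameter
#' vector passes the gate iff
#' `sign(f''(t1 - dt)) * sign(f''(t1 + dt)) < 0` and likewise at `t2`, with
#' `dt = 1` pseudotime rank. Draws failing the gate are rejected inside the
#' log posterior so that every retained draw carries two well-defined
#' inflection points.
#'
#' @param theta named double-sigmoidal parameter vector
#' @param dt window half-width in pseudotime ranks
#' @return logical scalar
#' @export
dsig_inflection_gate <- function(theta, dt = 1) {
  d2 <- function(t) second_derivative("double_sigmoidal", theta, t)
  s <- sign(d2(c(theta[["t1"]] - dt, theta[["t1"]] + dt,
    theta[["t2"]] - dt, theta[["t2"]] + dt)))
  (s[1] * s[2] < 0) && (s[3] * s[4] < 0)
}

# Vectorized gate over walker rows; column order k1,k2,t1,t2,bmin,bmid,bmax.
dsig_gate_batch <- function(theta, dt = 1) {
  f2 <- function(t) {
    sig_d2_term(theta[, 1L], theta[, 6L] - theta[, 5L], theta[, 3L], t) +
      sig_d2_term(theta[, 2L], theta[, 7L] - theta[, 6L], theta[, 4L], t)
  }
  s1 <- sign(f2(theta[, 3L] - dt)) * sign(f2(theta[, 3L] + dt))
  s2 <- sign(f2(theta[, 4L] - dt)) * sign(f2(theta[, 4L] + dt))
  (s1 < 0) & (s2 < 0)
}

# Inflection loci and signs for one draw of a non-uniform family.
# Returns a data.frame with columns time, sign (+1 up-, -1 down-regulation).
inflection_loci <- function(family, theta) {
  switch(family,
    gaussian = data.frame(
      time = c(theta[["t0"]] - theta[["sigma"]],
        theta[["t0"]] + theta[["sigma"]]),
      sign = c(1, -1)),
    sigmoidal = data.frame(
      time = theta[["t0"]],
      sign = as.numeric(sign(theta[["k"]]))),
    double_sigmoidal = data.frame(
      time = c(theta[["t1"]], theta[["t2"]]),
      sign = c(as.numeric(sign(theta[["bmid"]] - theta[["bmin"]])),
        as.numeric(sign(theta[["bmax"]] - theta[["bmid"]])))),
    stop("no inflection points for family ", family)
  )
}

#' Signed inflection points for every retained posterior draw
#'
#' For each retained MCMC draw the inflection loci are read off the
#' parameters: the Gaussian yields `(t0 - sigma, +1)` and `(t0 + sigma, -1)`;
#' the sigmoidal yields `(t0, sign(k))`; the double sigmoidal yields
#' `(t1, sign(bmid - bmin))` and `(t2, sign(bmax - bmid))`. Signs encode
#' up-regulation (+1) versus down-regulation (-1) at the switch.
#'
#' @param ps a `posterior_sample` from [prune_walkers()]
#' @return data.frame with columns `draw`, `locus` (1-based, ordered by time
#'   within a draw), `time`, `sign`; zero rows for the uniform family
#' @export
extract_inflections <- function(ps) {
  stopifnot(inherits(ps, "posterior_sample"))
  family <- ps$family
  if (family == "uniform") {
    return(data.frame(draw = integer(), locus = integer(),
      time = numeric(), sign = numeric()))
  }
  draws <- ps$draws
  n <- nrow(draws)
  if (family == "gaussian") {
    t0 <- draws[, "t0"]; s <- draws[, "sigma"]
    data.frame(
      draw = rep(seq_len(n), 2L),
      locus = rep(c(1L, 2L), each = n),
      time = c(t0 - s, t0 + s),
      sign = rep(c(1, -1), each = n))
  } else if (family == "sigmoidal") {
    data.frame(draw = seq_len(n), locus = 1L,
      time = draws[, "t0"], sign = as.numeric(sign(draws[, "k"])))
  } else {
    data.frame(
      draw = rep(seq_len(n), 2L),
      locus = rep(c(1L, 2L), each = n),
      time = c(draws[, "t1"], draws[, "t2"]),
      sign = c(sign(draws[, "bmid"] - draws[, "bmin"]),
        sign(draws[, "bmax"] - draws[, "bmid"])))
  }
}

#' Classify the dynamic expression pattern of a fitted gene
#'
#' Maps the winning family and its inflection signs to a dynamic class:
#' sigmoidal fits are state switches (up or down by slope sign); Gaussian fits
#' are transient up-regulation; double sigmoidal fits are transient up
#' (+ then -), transient down (- then +), stepwise up (+ +) or stepwise down
#' (- -); uniform fits carry no dynamics.
#'
#' @param family winning model family
#' @param signs numeric vector of inflection signs ordered by time (ignored
#'   for uniform and gaussian fits; length 1 for sigmoidal, 2 for double
#'   sigmoidal)
#' @return one of `"state_switch_up"`, `"state_switch_down"`,
#'   `"transient_up"`, `"transient_down"`, `"stepwise_up"`,
#'   `"stepwise_down"`, `"none"`
#' @export
classify_dynamics <- function(family, signs = numeric()) {
  family <- match.arg(family, MODEL_FAMILIES)
  switch(family,
    uniform = "none",
    gaussian = "transient_up",
    sigmoidal = if (signs[1] > 0) "state_switch_up" else "state_switch_down",
    double_sigmoidal = {
      key <- paste(ifelse(signs[1:2] > 0, "+", "-"), collapse = "")
      switch(key,
        "+-" = "transient_up",
        "-+" = "transient_down",
        "++" = "stepwise_up",
        "--" = "stepwise_down")
    }
  )
}
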