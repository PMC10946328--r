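#' Log-normalize a UMI count
#'
#' Maps raw counts into fit space via
#' \deqn{\tilde y = \ln\!\left(y \frac{\tilde M}{M_t} + 1\right)}
#' where `M_t` is the cell's total UMI count and the size factor `M_tilde` is
#' the median total across cells. The mapping is 0 iff `y = 0` and strictly
#' increasing in `y`.
#'
#' @param y nonnegative count(s)
#' @param M_t positive total UMI count of the cell(s)
#' @param M_tilde positive size factor (median cell total)
#' @return log-normalized value(s), >= 0
#' @export
lognormalize <- function(y, M_t, M_tilde) {
  if (any(M_t <= 0)) stop("M_t must be positive")
  if (M_tilde <= 0) stop("M_tilde must be positive")
  log1p(y * M_tilde / M_t)
}

#' Invert the log-normalization mapping
#'
#' Maps a fit-space value back to count space:
#' \eqn{(e^{\tilde y} - 1)\, M_t / \tilde M}. This is the exact inverse of
#' [lognormalize()] and is how fitted curve values become negative-binomial
#' means.
#'
#' @param ytilde fit-space value(s), >= 0
#' @inheritParams lognormalize
#' @return count-space value(s), >= 0
#' @export
inverse_lognormalize <- function(ytilde, M_t, M_tilde) {
  if (any(ytilde < 0)) stop("ytilde must be nonnegative")
  if (any(M_t <= 0)) stop("M_t must be positive")
  expm1(ytilde) * M_t / M_tilde
}

# Log-normalized profile of one gene across the ordered cells.
normalized_profile <- function(td, gene) {
  y <- td$counts[gene, ]
  lognormalize(y, td$M, td$M_tilde)
}

#' Estimate the global negative-binomial dispersion
#'
#' UMI count data are consistent with a single dispersion shared across genes;
#' per-gene dispersions overfit. The estimate deliberately uses genes whose
#' variability is mostly technical: per gene, the mean and variance of raw
#' counts are computed across cells; log10 means are split into `n_bins`
#' equally spaced bins; within each bin a linear fit of log10 variance on
#' log10 mean gives an expected variance, and genes in the top 20th percentile
#' of (observed - expected) variance excess are dropped. On the remaining
#' genes, `sigma^2 = mu + mu^2 / phi` is fit by nonlinear least squares over
#' `log(phi)` (initialized at `phi = 10`), all genes weighted equally.
#'
#' @param td a `trajectory_dataset`
#' @param n_bins number of log10-mean bins (falls back to 3 with a warning if
#'   fewer than 5 are nonempty)
#' @return object of class `dispersion_estimate`: list with `phi`,
#'   `fitted_gene_ids`, and `bin_report` (per-bin slope/intercept/size)
#' @export
estimate_global_dispersion <- function(td, n_bins = 5L) {
  counts <- td$counts
  mu <- rowMeans(counts)
  v <- apply(counts, 1L, stats::var)
  nz <- mu > 0
  if (sum(nz) < 50L) {
    stop("need at least 50 genes with nonzero mean count to estimate dispersion")
  }
  mu <- mu[nz]; v <- v[nz]
  ids <- rownames(counts)[nz]

  lmu <- log10(mu)
  assign_bins <- function(k) {
    edges <- seq(min(lmu), max(lmu), length.out = k + 1L)
    b <- findInterval(lmu, edges, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), k)
  }
  bins <- assign_bins(n_bins)
  if (length(unique(bins)) < 5L && n_bins >= 5L) {
    warning("fewer than 5 nonempty log10-mean bins; falling back to 3 bins")
    n_bins <- 3L
    bins <- assign_bins(n_bins)
  }

  keep <- logical(length(mu))
  bin_report <- data.frame(bin = seq_len(n_bins), slope = NA_real_,
    intercept = NA_real_, n_genes = 0L, n_kept = 0L)
  lv <- log10(pmax(v, .Machine$double.xmin))
  for (b in seq_len(n_bins)) {
    in_b <- which(bins == b)
    bin_report$n_genes[b] <- length(in_b)
    if (length(in_b) == 0L) next
    if (length(in_b) < 3L) {
      # too few points for a within-bin fit; keep all
      keep[in_b] <- TRUE
      bin_report$n_kept[b] <- length(in_b)
      next
    }
    fit <- stats::lm.fit(cbind(1, lmu[in_b]), lv[in_b])
    expected <- 10^(fit$coefficients[1] + fit$coefficients[2] * lmu[in_b])
    excess <- v[in_b] - expected
    thr <- stats::quantile(excess, 0.8, names = FALSE)
    sel <- excess <= thr   # drop strictly above the 80th percentile
    keep[in_b[sel]] <- TRUE
    bin_report$slope[b] <- fit$coefficients[2]
    bin_report$intercept[b] <- fit$coefficients[1]
    bin_report$n_kept[b] <- sum(sel)
  }

  mu_f <- mu[keep]; v_f <- v[keep]
  sse <- function(lphi) {
    phi <- exp(lphi)
    sum((v_f - mu_f - mu_f^2 / phi)^2)
  }
  # positivity enforced by optimizing over log(phi); start/scale around phi=10
  opt <- stats::optimize(sse, interval = log(c(1e-3, 1e15)))
  if (!is.finite(opt$objective)) {
    stop("dispersion least squares failed to converge; SSE = ", opt$objective,
      " at log(phi) = ", opt$minimum)
  }
  structure(list(
    phi = exp(opt$minimum),
    fitted_gene_ids = ids[keep],
    bin_report = bin_report,
    n_genes_used = sum(keep),
    sse = opt$objective
  ), class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("Global NB dispersion estimate\n")
  cat(sprintf("  phi = %.4g (fit on %d genes)\n", x$phi, x$n_genes_used))
  invisible(x)
}
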