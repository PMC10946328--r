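#' Fit one model family to one gene
#'
#' Convenience wrapper: walker initialization, ensemble MCMC, pruning, and
#' diagnostics for a single family.
#'
#' @inheritParams run_ensemble
#' @param diagnostics_t_max largest autocorrelation delay; capped at the
#'   post-burn-in chain length
#' @param compute_diagnostics set `FALSE` to skip the autocorrelation report
#' @return list with `ensemble` (`chain_ensemble`), `posterior`
#'   (`posterior_sample`), `diagnostics` (`diagnostics_report` or `NULL`)
#' @export
fit_gene_family <- function(family, td, gene, phi, n_iterations = 10000L,
                            burn_in = 5000L, seed = 1L,
                            diagnostics_t_max = 1000L,
                            compute_diagnostics = TRUE) {
  ce <- run_ensemble(family, td, gene, phi, n_iterations = n_iterations,
    burn_in = burn_in, seed = seed)
  t_max <- min(diagnostics_t_max, n_iterations - burn_in - 1L)
  list(ensemble = ce, posterior = prune_walkers(ce),
    diagnostics = if (compute_diagnostics) diagnostics(ce, T_max = t_max))
}

#' Fit all four families to one gene and select the best model
#'
#' Runs the ensemble sampler for the uniform, Gaussian, sigmoidal, and double
#' sigmoidal families, scores each with the subsample BIC on a shared subset
#' sequence, applies the selection cascade, and extracts signed inflection
#' points from the winning family's retained draws.
#'
#' @inheritParams run_ensemble
#' @param n_subsets number of random subsets for the BIC distribution
#' @param drop_frac fraction of cells dropped per subset
#' @return object of class `gene_fit`: list with `gene`, `selection`,
#'   `posterior` (winning family), `inflections`, `inflection_summary`
#'   (median, central 95% interval and majority sign per locus),
#'   `dynamic_class`, `diagnostics`, `phi`, `seed`
#' @export
fit_gene <- function(td, gene, phi, n_iterations = 10000L, burn_in = 5000L,
                     n_subsets = 10000L, drop_frac = 0.02, seed = 1L) {
  stopifnot(inherits(td, "trajectory_dataset"), gene %in% td$gene_ids)
  subsets <- make_subsets(td$N, n_subsets, drop_frac, seed = seed + 101L)
  fits <- list()
  sets <- list()
  for (i in seq_along(MODEL_FAMILIES)) {
    fam <- MODEL_FAMILIES[i]
    fits[[fam]] <- fit_gene_family(fam, td, gene, phi,
      n_iterations = n_iterations, burn_in = burn_in, seed = seed + i,
      compute_diagnostics = FALSE)
    sets[[fam]] <- subsample_bics(fits[[fam]]$posterior, td, gene, phi,
      subsets = subsets)
  }
  sel <- select_model(sets)
  winner <- fits[[sel$family]]
  winner$diagnostics <- diagnostics(winner$ensemble,
    T_max = min(1000L, n_iterations - burn_in - 1L))
  infl <- extract_inflections(winner$posterior)
  structure(list(
    gene = gene,
    selection = sel,
    posterior = winner$posterior,
    inflections = infl,
    inflection_summary = summarize_inflections(infl),
    dynamic_class = classify_dynamics(sel$family,
      signs = locus_signs(infl)),
    diagnostics = winner$diagnostics,
    phi = phi, seed = seed,
    n_iterations = n_iterations, burn_in = burn_in
  ), class = "gene_fit")
}

#' Build a `gene_fit` from a single-family posterior
#'
#' When the model family is known (or fixed by design) the full four-family
#' selection can be skipped; this wraps a pruned posterior sample into the
#' same `gene_fit` container that [fit_gene()] produces, so inflection-based
#' downstream steps ([order_cascade()], [infer_interaction()],
#' [screen_upstream_regulators()]) apply unchanged.
#'
#' @param ps a `posterior_sample`
#' @param diagnostics optional `diagnostics_report`
#' @return a `gene_fit` whose `selection` records the fixed family
#' @export
gene_fit_from_posterior <- function(ps, diagnostics = NULL) {
  stopifnot(inherits(ps, "posterior_sample"))
  infl <- extract_inflections(ps)
  structure(list(
    gene = ps$gene,
    selection = list(family = ps$family, branch = "fixed_family",
      summaries = NULL),
    posterior = ps,
    inflections = infl,
    inflection_summary = summarize_inflections(infl),
    dynamic_class = classify_dynamics(ps$family, signs = locus_signs(infl)),
    diagnostics = diagnostics
  ), class = "gene_fit")
}

# Majority sign per locus, ordered by locus index.
locus_signs <- function(infl) {
  if (!nrow(infl)) return(numeric())
  vapply(sort(unique(infl$locus)), function(l) {
    s <- infl$sign[infl$locus == l]
    as.numeric(names(which.max(table(s))))
  }, numeric(1))
}

# Posterior median, central 95% interval, and majority sign per locus.
summarize_inflections <- function(infl) {
  if (!nrow(infl)) {
    return(data.frame(locus = integer(), median = numeric(),
      lo95 = numeric(), hi95 = numeric(), sign = numeric()))
  }
  loci <- sort(unique(infl$locus))
  do.call(rbind, lapply(loci, function(l) {
    x <- infl$time[infl$locus == l]
    s <- infl$sign[infl$locus == l]
    data.frame(locus = l,
      median = stats::median(x),
      lo95 = stats::quantile(x, 0.025, names = FALSE),
      hi95 = stats::quantile(x, 0.975, names = FALSE),
      sign = as.numeric(names(which.max(table(s)))))
  }))
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("Gene %s: best fit %s (%s)\n", x$gene, x$selection$family,
    x$dynamic_class))
  if (nrow(x$inflection_summary)) {
    print(x$inflection_summary, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Fit the full trajectory
#'
#' Estimates the global dispersion (unless supplied), then fits and selects a
#' model for every gene in the dataset. Per-gene seeds are derived
#' deterministically from `seed` and the gene's position.
#'
#' @inheritParams fit_gene
#' @param genes genes to fit; defaults to all genes in `td`
#' @param phi global dispersion; estimated with
#'   [estimate_global_dispersion()] when `NULL`
#' @return object of class `trajectory_fit`: list with `fits` (named list of
#'   `gene_fit`), `phi`, `seed`, and the call's settings
#' @export
fit_trajectory <- function(td, genes = NULL, phi = NULL,
                           n_iterations = 10000L, burn_in = 5000L,
                           n_subsets = 10000L, drop_frac = 0.02, seed = 1L) {
  stopifnot(inherits(td, "trajectory_dataset"))
  if (is.null(genes)) genes <- td$gene_ids
  if (is.null(phi)) phi <- estimate_global_dispersion(td)$phi
  fits <- vector("list", length(genes))
  names(fits) <- genes
  for (i in seq_along(genes)) {
    fits[[i]] <- fit_gene(td, genes[i], phi,
      n_iterations = n_iterations, burn_in = burn_in,
      n_subsets = n_subsets, drop_frac = drop_frac,
      seed = seed + 997L * i)
  }
  structure(list(fits = fits, phi = phi, seed = seed,
    n_iterations = n_iterations, burn_in = burn_in,
    n_subsets = n_subsets, drop_frac = drop_frac),
    class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  fams <- vapply(x$fits, function(f) f$selection$family, "")
  cat(sprintf("Trajectory fit: %d genes, phi = %.3g\n", length(x$fits),
    x$phi))
  print(table(factor(fams, levels = MODEL_FAMILIES)))
  invisible(x)
}
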