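#' Configuration for a synthetic trajectory dataset
#'
#' Describes a pseudotime trajectory with `n_cells` cells, per-cell UMI
#' totals either constant or lognormal (default: median 5000, sdlog 0.3,
#' mimicking realistic droplet library-size spread and exercising the
#' size-factor normalization), a global NB dispersion `phi`, and a list of
#' gene specifications, each a list with `name`, `family`, and a true
#' parameter vector `theta` in fit space.
#'
#' @param n_cells number of cells N
#' @param genes list of gene specs: `list(name=, family=, theta=)`
#' @param phi global NB dispersion (> 0)
#' @param umi `"lognormal"` or `"constant"`
#' @param umi_median median per-cell UMI total (>= 100)
#' @param umi_sdlog lognormal sd on the log scale (ignored for constant)
#' @param seed integer seed
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_cells, genes, phi = 10,
                              umi = c("lognormal", "constant"),
                              umi_median = 5000, umi_sdlog = 0.3,
                              seed = 1L) {
  umi <- match.arg(umi)
  stopifnot(phi > 0, umi_median >= 100, n_cells >= 10)
  for (g in genes) {
    stopifnot(!is.null(g$name), g$family %in% MODEL_FAMILIES)
    bad <- check_parameters(g$family, g$theta, n_cells)
    if (!is.null(bad)) {
      stop("gene '", g$name, "': invalid true parameter '", bad, "'")
    }
  }
  structure(list(n_cells = n_cells, genes = genes, phi = phi, umi = umi,
    umi_median = umi_median, umi_sdlog = umi_sdlog, seed = seed),
    class = "simulation_config")
}

# Per-cell UMI totals for a config (deterministic given cfg$seed).
simulate_umi_totals <- function(cfg) {
  set.seed(cfg$seed)
  if (cfg$umi == "constant") {
    rep(as.integer(cfg$umi_median), cfg$n_cells)
  } else {
    pmax(100L, as.integer(round(stats::rlnorm(cfg$n_cells,
      meanlog = log(cfg$umi_median), sdlog = cfg$umi_sdlog))))
  }
}

#' Simulate NB counts for one gene along the trajectory
#'
#' Evaluates the true response function at `t = 1..N` in fit space, maps it to
#' count space with the inverse log-normalization (so the generative model
#' matches the likelihood being fit), and draws counts from
#' `NB(mu_t, phi)`. Cells where `mu_t = 0` deterministically yield 0.
#'
#' @param family true model family
#' @param theta true parameter vector (fit space)
#' @param M per-cell UMI totals
#' @param M_tilde size factor (median of `M`)
#' @param phi NB dispersion
#' @param seed integer seed
#' @return integer vector of counts over `t = 1..N`
#' @export
simulate_gene <- function(family, theta, M, M_tilde = stats::median(M),
                          phi = 10, seed = 1L) {
  set.seed(seed)
  N <- length(M)
  f <- evaluate_model(family, theta, seq_len(N), N)
  mu <- inverse_lognormalize(pmax(f, 0), M, M_tilde)
  y <- integer(N)
  pos <- mu > 0
  y[pos] <- stats::rnbinom(sum(pos), size = phi, mu = mu[pos])
  y
}

#' Generate a full synthetic benchmark dataset
#'
#' Builds a `count_matrix`, a pseudotime table (rank / N), and a truth table
#' recording each gene's generating family, parameters, and closed-form
#' inflection times/signs, all deterministically from the config seed. When
#' `out_dir` is given, the count matrix is additionally written as a Matrix
#' Market file with gene/cell sidecars plus `pseudotime.tsv` and `truth.tsv`,
#' in exactly the dialects [read_count_matrix()] and [read_pseudotime()]
#' consume.
#'
#' @param cfg a `simulation_config`
#' @param out_dir optional output directory for on-disk fixtures
#' @return list with `cm` (count_matrix), `pt` (pseudotime data.frame),
#'   `td` (assembled trajectory_dataset), `truth` (data.frame)
#' @export
make_benchmark_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  N <- cfg$n_cells
  M <- simulate_umi_totals(cfg)
  M_tilde <- stats::median(M)
  cells <- sprintf("cell%04d", seq_len(N))

  counts <- matrix(0, length(cfg$genes), N,
    dimnames = list(vapply(cfg$genes, `[[`, "", "name"), cells))
  truth <- list()
  for (i in seq_along(cfg$genes)) {
    g <- cfg$genes[[i]]
    counts[i, ] <- simulate_gene(g$family, g$theta, M, M_tilde, cfg$phi,
      seed = cfg$seed + 1000L + i)
    infl <- if (g$family == "uniform") {
      data.frame(time = numeric(), sign = numeric())
    } else {
      inflection_loci(g$family, g$theta)
    }
    truth[[i]] <- data.frame(
      gene = g$name, family = g$family,
      params = paste(sprintf("%s=%.10g", names(g$theta), g$theta),
        collapse = ";"),
      inflection1_time = if (nrow(infl) >= 1) infl$time[1] else NA_real_,
      inflection1_sign = if (nrow(infl) >= 1) infl$sign[1] else NA_real_,
      inflection2_time = if (nrow(infl) >= 2) infl$time[2] else NA_real_,
      inflection2_sign = if (nrow(infl) >= 2) infl$sign[2] else NA_real_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  # pad library size so every cell reaches its target total: a spacer gene
  # absorbs the difference between gene counts and the intended M_t
  used <- colSums(counts)
  spacer <- pmax(M - used, 0)
  counts <- rbind(counts, spacer = spacer)

  cm <- structure(list(gene_ids = rownames(counts), cell_ids = cells,
    counts = counts), class = "count_matrix")
  pt <- data.frame(cell_id = cells, pseudotime = seq_len(N) / N)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
      "generalMatrix"), file.path(out_dir, "counts.mtx"))
    writeLines(rownames(counts), file.path(out_dir, "genes.txt"))
    writeLines(cells, file.path(out_dir, "cells.txt"))
    utils::write.table(pt, file.path(out_dir, "pseudotime.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }

  list(cm = cm, pt = pt, td = build_trajectory(cm, pt), truth = truth)
}
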