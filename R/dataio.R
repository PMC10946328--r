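#' Read a gene-by-cell UMI count matrix
#'
#' Supports Matrix Market coordinate files (with plain-text gene and cell
#' sidecar files, one identifier per line) and dense TSV files with a header
#' row of cell identifiers and a first column of gene identifiers. Duplicate
#' Matrix Market coordinate entries are summed. Orientation is auto-detected:
#' if the gene sidecar length matches the row count the matrix is taken as
#' genes x cells, if it matches the column count the matrix is transposed;
#' `transpose` overrides the auto-detection.
#'
#' @param path_matrix path to a `.mtx` Matrix Market file or a TSV
#' @param path_genes path to the gene-identifier sidecar (required for
#'   Matrix Market input)
#' @param path_cells path to the cell-identifier sidecar (required for
#'   Matrix Market input)
#' @param transpose `NULL` for auto-detection, otherwise force (`TRUE`) or
#'   forbid (`FALSE`) transposition of the stored matrix
#' @return object of class `count_matrix`: list with `gene_ids`, `cell_ids`,
#'   and an integer `counts` matrix (genes x cells)
#' @export
read_count_matrix <- function(path_matrix, path_genes = NULL,
                              path_cells = NULL, transpose = NULL) {
  if (!file.exists(path_matrix)) stop("no such file: ", path_matrix)
  first <- readLines(path_matrix, n = 1L)
  is_mm <- grepl("^%%MatrixMarket", first) ||
    grepl("\\.mtx$", path_matrix, ignore.case = TRUE)

  if (is_mm) {
    if (is.null(path_genes) || is.null(path_cells)) {
      stop("Matrix Market input requires gene and cell sidecar files")
    }
    m <- tryCatch(Matrix::readMM(path_matrix), error = function(e) {
      stop("failed to parse Matrix Market file '", path_matrix, "': ",
        conditionMessage(e))
    })
    # CsparseMatrix conversion sums duplicated coordinate entries
    m <- as.matrix(methods::as(m, "CsparseMatrix"))
    genes <- readLines(path_genes)
    cells <- readLines(path_cells)
    if (is.null(transpose)) {
      if (length(genes) == nrow(m) && length(cells) == ncol(m)) {
        transpose <- FALSE
      } else if (length(genes) == ncol(m) && length(cells) == nrow(m)) {
        transpose <- TRUE
      } else {
        stop("sidecar lengths (", length(genes), " genes, ", length(cells),
          " cells) match neither orientation of the ", nrow(m), " x ",
          ncol(m), " matrix")
      }
    }
    if (transpose) m <- t(m)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop("sidecar lengths do not match matrix dimensions")
    }
  } else {
    df <- tryCatch(
      utils::read.delim(path_matrix, check.names = FALSE, row.names = 1L),
      error = function(e) {
        stop("failed to parse TSV count matrix '", path_matrix, "': ",
          conditionMessage(e))
      })
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(as.numeric(m))))[1L]
      stop("non-numeric count entry near data line ",
        ((bad - 1L) %% nrow(m)) + 1L, " of '", path_matrix, "'")
    }
    genes <- rownames(df)
    cells <- colnames(df)
    if (isTRUE(transpose)) {
      m <- t(m); tmp <- genes; genes <- cells; cells <- tmp
    }
  }

  if (any(m < 0)) {
    stop("negative count entries found in '", path_matrix, "'")
  }
  if (any(m != round(m))) {
    stop("non-integer count entries found in '", path_matrix, "'")
  }
  if (anyDuplicated(genes)) stop("duplicated gene identifiers")
  if (anyDuplicated(cells)) stop("duplicated cell identifiers")
  storage.mode(m) <- "double"
  dimnames(m) <- list(genes, cells)
  structure(list(gene_ids = genes, cell_ids = cells, counts = m),
    class = "count_matrix")
}

#' Read a per-cell pseudotime table
#'
#' @param path TSV with columns `cell_id` and `pseudotime`
#' @return data.frame with those two columns
#' @export
read_pseudotime <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
    colClasses = c(cell_id = "character"))
  if (!all(c("cell_id", "pseudotime") %in% names(df))) {
    stop("pseudotime table must have columns 'cell_id' and 'pseudotime'")
  }
  if (!is.numeric(df$pseudotime)) stop("pseudotime values must be numeric")
  df[, c("cell_id", "pseudotime")]
}

#' Assemble the pseudotime-ordered trajectory dataset
#'
#' Orders the counted cells by ascending pseudotime (ties broken by
#' lexicographic cell identifier for a deterministic ranking), computes
#' per-cell UMI totals `M_t` and the size factor `M_tilde = median(M_t)`, and
#' assigns pseudotime ranks `t = 1..N`. Cells present in the count matrix but
#' absent from the pseudotime table are dropped with a message; pseudotime
#' entries naming unknown cells are an error. Cells with zero total UMIs are
#' rejected, since the size-factor normalization is undefined for them.
#'
#' @param cm a `count_matrix`
#' @param pt data.frame with columns `cell_id`, `pseudotime`
#' @return object of class `trajectory_dataset`: list with `gene_ids`,
#'   `cell_ids` (ordered), `counts` (reordered genes x cells), `pseudotime`,
#'   `M` (per-cell totals), `M_tilde`, `N`
#' @export
build_trajectory <- function(cm, pt) {
  stopifnot(inherits(cm, "count_matrix"))
  unknown <- setdiff(pt$cell_id, cm$cell_ids)
  if (length(unknown)) {
    stop("pseudotime table references cells absent from the count matrix: ",
      paste(utils::head(unknown, 10), collapse = ", "))
  }
  if (anyDuplicated(pt$cell_id)) {
    stop("duplicated cell identifiers in the pseudotime table")
  }
  dropped <- setdiff(cm$cell_ids, pt$cell_id)
  if (length(dropped)) {
    message("dropping ", length(dropped),
      " cell(s) without a pseudotime value")
  }
  ord <- order(pt$pseudotime, pt$cell_id)
  cells <- pt$cell_id[ord]
  counts <- cm$counts[, cells, drop = FALSE]
  N <- length(cells)
  if (N < 10L) stop("too few cells to fit (N = ", N, " < 10)")
  M <- colSums(counts)
  zero <- cells[M == 0]
  if (length(zero)) {
    stop("cells with zero total UMIs (size factor undefined): ",
      paste(utils::head(zero, 10), collapse = ", "))
  }
  structure(list(
    gene_ids = cm$gene_ids, cell_ids = cells, counts = counts,
    pseudotime = pt$pseudotime[ord], M = unname(M),
    M_tilde = stats::median(M), N = N
  ), class = "trajectory_dataset")
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat(sprintf(
    "Trajectory dataset: %d genes x %d cells, median UMI total %.1f\n",
    length(x$gene_ids), x$N, x$M_tilde))
  invisible(x)
}

#' Filter genes by expression prevalence
#'
#' Retains genes with a nonzero count in at least
#' `min_expressed_frac * N` cells (boundary inclusive); gene order is
#' preserved. Per-cell totals and the size factor are unchanged (they are
#' properties of the cells).
#'
#' @param td a `trajectory_dataset`
#' @param min_expressed_frac fraction in `[0, 1]`; the default keeps genes
#'   expressed in at least 1% of cells
#' @return filtered `trajectory_dataset`
#' @export
filter_genes <- function(td, min_expressed_frac = 0.01) {
  stopifnot(inherits(td, "trajectory_dataset"),
    min_expressed_frac >= 0, min_expressed_frac <= 1)
  n_expr <- rowSums(td$counts > 0)
  keep <- n_expr >= min_expressed_frac * td$N
  if (!any(keep)) message("gene filter removed all genes")
  td$counts <- td$counts[keep, , drop = FALSE]
  td$gene_ids <- td$gene_ids[keep]
  td
}

#' Write fit results to disk
#'
#' Writes (a) `summary.tsv` with one row per gene (best family, decision
#' branch, dynamic class, mean parameters of the winning family, per-family
#' subsample-BIC summaries, inflection posterior medians / 95% intervals /
#' signs, and acceptance diagnostics), (b) one posterior-sample TSV per gene
#' under `samples/` (one row per retained draw: parameters, log posterior,
#' inflection times and signs), and (c) `run_metadata.json` recording the
#' seed, iteration counts, dispersion, size factor, and package version.
#'
#' @param results list of `gene_fit` objects from [fit_gene()]
#' @param out_dir output directory (created if missing)
#' @param metadata named list merged into the run-metadata record
#' @return invisibly, the paths written
#' @export
write_fit_results <- function(results, out_dir, metadata = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "samples"), showWarnings = FALSE)

  summ <- fit_summary(results)
  path_summary <- file.path(out_dir, "summary.tsv")
  utils::write.table(summ, path_summary, sep = "\t", quote = FALSE,
    row.names = FALSE)

  sample_paths <- character(0)
  for (fit in results) {
    tab <- sample_table(fit)
    p <- file.path(out_dir, "samples", paste0(fit$gene, ".tsv"))
    utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = NA),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    sample_paths <- c(sample_paths, p)
  }

  meta <- c(list(
    package = "cascadefit",
    version = as.character(utils::packageVersion("cascadefit")),
    n_genes = length(results)
  ), metadata)
  path_meta <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, path_meta, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(summary = path_summary, samples = sample_paths,
    metadata = path_meta))
}

# One row per retained draw of the winning family, with inflection columns.
sample_table <- function(fit) {
  ps <- fit$posterior
  tab <- as.data.frame(ps$draws)
  tab <- cbind(draw = seq_len(nrow(tab)), tab, log_post = ps$log_post)
  infl <- fit$inflections
  if (nrow(infl)) {
    for (l in sort(unique(infl$locus))) {
      sub <- infl[infl$locus == l, ]
      sub <- sub[order(sub$draw), ]
      tab[[paste0("inflection", l, "_time")]] <- sub$time
      tab[[paste0("inflection", l, "_sign")]] <- sub$sign
    }
  }
  tab
}

#' Read back a posterior-sample table written by [write_fit_results()]
#' @param path path to a per-gene sample TSV
#' @return data.frame of retained draws
#' @export
read_fit_samples <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Summary table for a collection of gene fits
#'
#' @param results list of `gene_fit` objects
#' @return data.frame with one row per gene
#' @export
fit_summary <- function(results) {
  rows <- lapply(results, function(fit) {
    sel <- fit$selection
    s <- sel$summaries
    row <- data.frame(
      gene = fit$gene,
      best_family = sel$family,
      decision_branch = sel$branch,
      dynamic_class = fit$dynamic_class,
      stringsAsFactors = FALSE
    )
    for (fam in MODEL_FAMILIES) {
      i <- match(fam, s$family)
      row[[paste0("bic_mean_", fam)]] <- s$bic_mean[i]
      row[[paste0("bic_min_", fam)]] <- s$bic_min[i]
      row[[paste0("bic_max_", fam)]] <- s$bic_max[i]
    }
    row$mean_params <- paste(
      sprintf("%s=%.6g", names(fit$posterior$theta_mean),
        fit$posterior$theta_mean),
      collapse = ";")
    for (l in 1:2) {
      il <- fit$inflection_summary[fit$inflection_summary$locus == l, ]
      row[[paste0("inflection", l, "_median")]] <-
        if (nrow(il)) il$median else NA_real_
      row[[paste0("inflection", l, "_lo95")]] <-
        if (nrow(il)) il$lo95 else NA_real_
      row[[paste0("inflection", l, "_hi95")]] <-
        if (nrow(il)) il$hi95 else NA_real_
      row[[paste0("inflection", l, "_sign")]] <-
        if (nrow(il)) il$sign else NA_real_
    }
    row$mean_acceptance <- mean(fit$posterior$acceptance_fraction)
    row$min_ess <- if (is.null(fit$diagnostics)) NA_real_ else
      min(fit$diagnostics$ess)
    row
  })
  if (!length(rows)) return(empty_summary())
  do.call(rbind, rows)
}

empty_summary <- function() {
  cols <- c("gene", "best_family", "decision_branch", "dynamic_class",
    paste0(c("bic_mean_", "bic_min_", "bic_max_"),
      rep(MODEL_FAMILIES, each = 3L)),
    "mean_params",
    paste0(rep(paste0("inflection", 1:2), each = 4L),
      c("_median", "_lo95", "_hi95", "_sign")),
    "mean_acceptance", "min_ess")
  df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
  names(df) <- cols
  df
}
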