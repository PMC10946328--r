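#' Overlap between two genes' inflection-time distributions
#'
#' The posterior samples of one inflection locus per gene are binned into 100
#' equally spaced bins spanning the pooled minimum to the pooled maximum over
#' both sample sets (final bin right-closed). With `p_A(x_i)` and `p_B(x_i)`
#' the histogram fractions, the overlap is
#' \deqn{P(A = B) = \sum_{i=1}^{100} \min(p_A(x_i), p_B(x_i)),}
#' which also serves as the p-value-style "percentage of overlapping
#' inflection point estimates". When all samples across both sets are
#' identical the range is degenerate and the overlap is 1 by convention.
#'
#' @param samples_a numeric vector of inflection-time samples for gene A
#' @param samples_b numeric vector for gene B
#' @param n_bins number of bins (100 by default)
#' @return object of class `overlap_estimate`: list with `overlap`, `breaks`,
#'   `p_a`, `p_b`
#' @export
inflection_overlap <- function(samples_a, samples_b, n_bins = 100L) {
  stopifnot(length(samples_a) > 0, length(samples_b) > 0)
  lo <- min(samples_a, samples_b)
  hi <- max(samples_a, samples_b)
  if (lo == hi) {
    return(structure(list(overlap = 1, breaks = c(lo, hi),
      p_a = 1, p_b = 1), class = "overlap_estimate"))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- function(x) {
    b <- findInterval(x, breaks, rightmost.closed = TRUE)
    tabulate(pmin(pmax(b, 1L), n_bins), nbins = n_bins)
  }
  p_a <- bin(samples_a) / length(samples_a)
  p_b <- bin(samples_b) / length(samples_b)
  structure(list(
    overlap = sum(pmin(p_a, p_b)),
    breaks = breaks, p_a = p_a, p_b = p_b
  ), class = "overlap_estimate")
}

# Convenience container for one inflection locus of a fitted gene.
# sign: +1/-1; samples: posterior inflection times; median taken if missing.
inflection_locus <- function(gene, samples, sign, median_time = NULL) {
  list(gene = gene, samples = samples, sign = sign,
    median = if (is.null(median_time)) stats::median(samples) else median_time)
}

#' Infer a directed regulatory interaction from inflection timing
#'
#' Compares one inflection locus per gene. If the two genes' inflection-time
#' distributions overlap by at least `overlap_threshold` (default 1%), the
#' switches are considered simultaneous: equal signs give a mutual positive
#' interaction, opposite signs a mutual negative one. Otherwise the genes are
#' ordered by median inflection time and the sign pattern
#' (earlier, later) maps to: (+,+) earlier positively regulates later;
#' (+,-) earlier negatively regulates later and later positively regulates
#' earlier; (-,-) earlier positively regulates later; (-,+) no relationship.
#'
#' @param locus_a,locus_b lists as returned by [gene_inflection_locus()] (or
#'   any list with `gene`, `samples`, `sign`, `median`)
#' @param overlap_threshold minimum overlap treated as simultaneous
#' @return data.frame of directed edges with columns `source`, `target`,
#'   `relation` (`positive`, `negative`, `mutual_positive`,
#'   `mutual_negative`, `none`), `overlap`, `source_median`, `target_median`
#' @export
infer_interaction <- function(locus_a, locus_b, overlap_threshold = 0.01) {
  ov <- inflection_overlap(locus_a$samples, locus_b$samples)$overlap
  edge <- function(src, tgt, rel) {
    data.frame(source = src$gene, target = tgt$gene, relation = rel,
      overlap = ov, source_median = src$median, target_median = tgt$median,
      stringsAsFactors = FALSE)
  }
  if (ov >= overlap_threshold) {
    rel <- if (locus_a$sign == locus_b$sign) "mutual_positive" else
      "mutual_negative"
    return(rbind(edge(locus_a, locus_b, rel), edge(locus_b, locus_a, rel)))
  }
  if (locus_a$median <= locus_b$median) {
    first <- locus_a; second <- locus_b
  } else {
    first <- locus_b; second <- locus_a
  }
  key <- paste0(ifelse(first$sign > 0, "+", "-"),
    ifelse(second$sign > 0, "+", "-"))
  out <- switch(key,
    "++" = rbind(edge(first, second, "positive"),
      edge(second, first, "none")),
    "+-" = rbind(edge(first, second, "negative"),
      edge(second, first, "positive")),
    "--" = rbind(edge(first, second, "positive"),
      edge(second, first, "none")),
    "-+" = rbind(edge(first, second, "none"),
      edge(second, first, "none"))
  )
  # report in (A, B) order regardless of timing
  out[match(c(locus_a$gene, locus_b$gene), out$source), ]
}

#' Extract one inflection locus of a fitted gene
#'
#' @param fit a `gene_fit` (non-uniform winning family)
#' @param locus which inflection (1 = first in time; sigmoidal fits have
#'   only one)
#' @return list with `gene`, `samples`, `sign`, `median`
#' @export
gene_inflection_locus <- function(fit, locus = 1L) {
  if (fit$selection$family == "uniform") {
    stop("gene '", fit$gene, "' has a uniform fit; no inflection to compare")
  }
  infl <- fit$inflections[fit$inflections$locus == locus, ]
  if (!nrow(infl)) {
    stop("gene '", fit$gene, "' has no inflection locus ", locus)
  }
  sgn <- as.numeric(names(which.max(table(infl$sign))))
  inflection_locus(fit$gene, infl$time, sgn)
}

#' Order genes along the transcriptional cascade
#'
#' Sorts non-uniform fits by the posterior median of each gene's first
#' inflection time (ties broken by gene identifier), yielding the cascade
#' ordering in which expression switches occur along the trajectory.
#'
#' @param results list of `gene_fit` objects
#' @return object of class `cascade_ordering`: data.frame with one row per
#'   non-uniform gene, sorted by `first_inflection_median`
#' @export
order_cascade <- function(results) {
  keep <- Filter(function(f) f$selection$family != "uniform", results)
  if (!length(keep)) {
    out <- data.frame(gene = character(), family = character(),
      dynamic_class = character(), first_inflection_median = numeric(),
      first_inflection_sign = numeric())
    class(out) <- c("cascade_ordering", "data.frame")
    return(out)
  }
  rows <- lapply(keep, function(f) {
    loc <- gene_inflection_locus(f, 1L)
    data.frame(gene = f$gene, family = f$selection$family,
      dynamic_class = f$dynamic_class,
      first_inflection_median = loc$median,
      first_inflection_sign = loc$sign,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$first_inflection_median, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("cascade_ordering", "data.frame")
  out
}

#' Screen candidate upstream regulators of a target gene
#'
#' A candidate transcription factor is called a positive upstream regulator of
#' the target when it has a positive inflection point occurring simultaneously
#' with (overlap >= `overlap_threshold`) or before the target's first
#' inflection point, or a negative inflection point occurring after the
#' target's first inflection point. Candidates flagged as co-regulators
#' (co-activators/co-repressors) are held to a stricter rule: they must show a
#' transient up-regulation with their first inflection simultaneous with or
#' before the target's.
#'
#' @param target a `gene_fit` with a non-uniform winning family
#' @param candidates list of `gene_fit` objects (uniform fits are skipped)
#' @param coregulator_ids optional character vector of candidate genes to be
#'   screened under the co-regulator rule instead of the transcription-factor
#'   rule
#' @param overlap_threshold overlap treated as "simultaneous"
#' @return data.frame of accepted regulators with the locus and rule that
#'   admitted each
#' @export
screen_upstream_regulators <- function(target, candidates,
                                       coregulator_ids = NULL,
                                       overlap_threshold = 0.01) {
  if (target$selection$family == "uniform") {
    stop("target gene '", target$gene,
      "' has a uniform fit; no inflection point to anchor the screen")
  }
  tgt <- gene_inflection_locus(target, 1L)
  rows <- list()
  for (fit in candidates) {
    if (identical(fit$gene, target$gene)) next
    if (fit$selection$family == "uniform") next
    loci <- sort(unique(fit$inflections$locus))
    is_coreg <- !is.null(coregulator_ids) && fit$gene %in% coregulator_ids
    for (l in loci) {
      loc <- gene_inflection_locus(fit, l)
      ov <- inflection_overlap(loc$samples, tgt$samples)$overlap
      simultaneous <- ov >= overlap_threshold
      hit <- NULL
      if (is_coreg) {
        if (l == 1L && fit$dynamic_class == "transient_up" &&
            loc$sign > 0 && (simultaneous || loc$median < tgt$median)) {
          hit <- "coregulator_transient_up"
        }
      } else {
        if (loc$sign > 0 && (simultaneous || loc$median < tgt$median)) {
          hit <- "positive_before_or_simultaneous"
        } else if (loc$sign < 0 && loc$median > tgt$median) {
          hit <- "negative_after"
        }
      }
      if (!is.null(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = fit$gene, locus = l, sign = loc$sign,
          median = loc$median, overlap_with_target = ov, rule = hit,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), locus = integer(),
      sign = numeric(), median = numeric(), overlap_with_target = numeric(),
      rule = character()))
  }
  out <- do.call(rbind, rows)
  # one row per gene: earliest qualifying locus
  out <- out[order(out$gene, out$locus), ]
  out[!duplicated(out$gene), , drop = FALSE]
}
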