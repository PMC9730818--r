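#' Permutation test for DSB-feature overlap enrichment
#'
#' Tests whether the observed number of DSB intervals overlapping a chromatin
#' feature exceeds what per-chromosome random placement produces. Each
#' iteration re-places every DSB uniformly at random within its own
#' chromosome, keeping its length (the shuffle null of
#' \code{\link{shuffle_intervals}}), and records how many shuffled DSBs
#' overlap the feature by at least 1 bp. The empirical p-value is the fraction
#' of iterations in which the shuffled overlap count was equal to or higher
#' than the observed count; a zero exceedance count is displayed as the bound
#' \code{p < 1/n_iterations}.
#'
#' The test is one-sided (enrichment only). Iterations draw from
#' per-iteration substreams of the master seed, so results are deterministic
#' given \code{(inputs, seed, n_iterations)} and independent of iteration
#' order.
#'
#' @param dsbs \code{GRanges} of DSB regions
#' @param feature \code{GRanges} of the chromatin feature
#' @param genome a \code{\link{genome}}; defaults to the genome bound to
#'   \code{dsbs}
#' @param n_iterations number of shuffles (default 1000)
#' @param seed master seed
#' @return an object of class \code{enrichment_result} with fields
#'   \code{observed}, \code{null_counts}, \code{n_iterations}, \code{p_value},
#'   \code{p_display}, \code{seed}, \code{query}, \code{reference}
#' @export
permutation_enrichment <- function(dsbs, feature, genome = NULL,
                                   n_iterations = 1000L, seed = 1L) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  genome <- if (is.null(genome)) genome_of(dsbs) else as_genome(genome)
  if (length(dsbs) == 0) {
    warning("empty DSB set: p-value is 1 by construction")
    return(new_enrichment_result(0L, rep(0L, n_iterations), n_iterations,
                                 seed, dsbs, feature))
  }
  observed <- count_overlapping(dsbs, feature)
  chroms <- as.character(GenomeInfoDb::seqnames(dsbs))
  w <- GenomicRanges::width(dsbs)
  L <- as.numeric(genome[chroms])
  if (any(is.na(L) | w > L)) stop("DSB intervals incompatible with genome")
  idx <- overlap_index(feature, genome)
  iter_seeds <- vapply(seq_len(n_iterations), function(i)
    substream_seed(seed, paste0("iter", i)), integer(1))
  null_counts <- vapply(iter_seeds, function(s) {
    start0 <- with_seed(s, draw_starts(L, w))
    count_overlapping_fast(idx, chroms, start0, w)
  }, integer(1))
  new_enrichment_result(observed, null_counts, n_iterations, seed, dsbs, feature)
}

new_enrichment_result <- function(observed, null_counts, n_iterations, seed,
                                  dsbs, feature) {
  exceed <- sum(null_counts >= observed)
  p <- exceed / n_iterations
  structure(list(
    observed = observed,
    null_counts = null_counts,
    n_iterations = as.integer(n_iterations),
    p_value = p,
    p_display = if (exceed == 0) sprintf("p < %g", 1 / n_iterations)
                else sprintf("p = %g", p),
    seed = seed,
    query = S4Vectors::metadata(dsbs)$label %||% "query",
    reference = S4Vectors::metadata(feature)$label %||% "reference"),
    class = "enrichment_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Permutation overlap enrichment: %s vs %s\n", x$query, x$reference))
  cat(sprintf("  observed overlaps : %d\n", x$observed))
  cat(sprintf("  null mean (range) : %.1f (%d-%d) over %d iterations\n",
              mean(x$null_counts), min(x$null_counts), max(x$null_counts),
              x$n_iterations))
  cat(sprintf("  %s   [seed %s]\n", x$p_display, format(x$seed)))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(query = x$query, reference = x$reference, observed = x$observed,
             null_mean = mean(x$null_counts), n_iterations = x$n_iterations,
             p_value = x$p_value, p_display = x$p_display, seed = x$seed)
}
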