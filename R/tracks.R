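#' Mean signal of a stepwise-constant track over regions
#'
#' Base-pair-weighted average of track values across each region, the
#' average-over-bed semantics used to summarize ChIP signal or GP-seq scores
#' over DSB regions. With \code{uncovered_as_zero = TRUE} (the "mean0"
#' convention) uncovered bases contribute zeros and the sum is divided by the
#' full region length; otherwise the divisor is the number of covered bases
#' ("mean"), and a region touching no segment scores \code{NA}.
#'
#' @param track \code{GRanges} with a numeric \code{score} column; segments
#'   must not overlap within a chromosome
#' @param regions \code{GRanges}
#' @param uncovered_as_zero logical (default \code{TRUE})
#' @return numeric vector along \code{regions}
#' @export
mean_signal_over_region <- function(track, regions, uncovered_as_zero = TRUE) {
  if (!"score" %in% names(S4Vectors::mcols(track)))
    stop("signal track needs a 'score' metadata column")
  n <- length(regions)
  sums <- numeric(n)
  covered <- numeric(n)
  if (length(track) > 0 && n > 0) {
    hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      bp <- pmin(GenomicRanges::end(regions)[q], GenomicRanges::end(track)[s]) -
        pmax(GenomicRanges::start(regions)[q], GenomicRanges::start(track)[s]) + 1
      sums <- as.numeric(tapply(bp * track$score[s], factor(q, levels = seq_len(n)), sum))
      covered <- as.numeric(tapply(bp, factor(q, levels = seq_len(n)), sum))
      sums[is.na(sums)] <- 0
      covered[is.na(covered)] <- 0
    }
  }
  if (uncovered_as_zero) {
    sums / GenomicRanges::width(regions)
  } else {
    ifelse(covered > 0, sums / covered, NA_real_)
  }
}

#' Convert scored, non-overlapping bins to a signal track
#'
#' Lossless ingestion of binned score tables (e.g. 1-Mb GP-seq scores) into
#' the stepwise-constant track representation.
#'
#' @param bins \code{GRanges} with a numeric \code{score} column,
#'   non-overlapping
#' @return sorted \code{GRanges} signal track
#' @export
binned_track_from_intervals <- function(bins) {
  validate_track(bins)
}
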