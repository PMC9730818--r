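#' Count query intervals overlapping a reference set
#'
#' An interval "hits" the reference when it shares at least
#' \code{min_overlap_bp} bases with at least one reference interval; each
#' query interval is counted at most once, matching the convention of counting
#' how many DSBs overlap a chromatin feature. Coordinates are half-open on
#' disk, so a query ending where a reference starts does not overlap it.
#' Strand is ignored throughout.
#'
#' @param query,reference \code{GRanges}
#' @param min_overlap_bp minimum shared bases (default 1)
#' @return nonnegative integer count of query intervals hit
#' @export
count_overlapping <- function(query, reference, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1)
  check_same_genome(query, reference)
  if (length(reference) == 0 || length(query) == 0) return(0L)
  hits <- GenomicRanges::countOverlaps(query, reference,
                                       minoverlap = as.integer(min_overlap_bp),
                                       ignore.strand = TRUE)
  sum(hits > 0L)
}

#' Edge-to-edge gap from each query interval to the nearest reference interval
#'
#' Returns 0 for queries overlapping (or directly abutting) a reference
#' interval, otherwise the number of bases between the closest edges on the
#' same chromosome, and \code{NA} for queries on chromosomes carrying no
#' reference interval.
#'
#' @param query,reference \code{GRanges}
#' @return integer vector along \code{query}
#' @export
nearest_gap <- function(query, reference) {
  if (length(reference) == 0) stop("reference set is empty")
  out <- rep(NA_integer_, length(query))
  if (length(query) == 0) return(out)
  hits <- GenomicRanges::distanceToNearest(query, reference, ignore.strand = TRUE)
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Randomly re-place intervals within their chromosomes
#'
#' The permutation null used by the enrichment test: every interval keeps its
#' chromosome and its length and receives a uniformly random start over all
#' in-bounds placements. Shuffled intervals may overlap one another and may
#' overlap their original positions; per-chromosome interval counts and the
#' length multiset are preserved exactly.
#'
#' @param x \code{GRanges} to shuffle
#' @param genome a \code{\link{genome}}; defaults to the genome bound to
#'   \code{x}
#' @param seed integer seed; the shuffle is deterministic given the seed
#' @return \code{GRanges} parallel to \code{x} (names and metadata preserved)
#' @export
shuffle_intervals <- function(x, genome = NULL, seed = NULL) {
  genome <- if (is.null(genome)) genome_of(x) else as_genome(genome)
  chroms <- as.character(GenomeInfoDb::seqnames(x))
  w <- GenomicRanges::width(x)
  L <- as.numeric(genome[chroms])
  if (any(is.na(L))) stop("intervals on chromosomes absent from genome")
  if (any(w > L)) {
    i <- which(w > L)[1]
    stop(sprintf("interval %d is longer (%d bp) than its chromosome %s (%d bp)",
                 i, w[i], chroms[i], as.integer(L[i])))
  }
  start0 <- with_seed(seed, draw_starts(L, w))
  out <- GenomicRanges::GRanges(chroms, IRanges::IRanges(start = start0 + 1, width = w),
                                seqinfo = genome_seqinfo(genome))
  names(out) <- names(x)
  S4Vectors::mcols(out) <- S4Vectors::mcols(x)
  out
}

# Uniform 0-based starts over {0 .. L - w}; runif over [0, L-w+1) then floor.
draw_starts <- function(L, w) {
  pmin(floor(stats::runif(length(w), 0, L - w + 1)), L - w)
}

# --- fast overlap machinery for the permutation loop -------------------------
#
# Reference intervals are merged per chromosome and laid out on a single
# numeric axis (one spacer base between chromosomes so merging cannot bridge
# them). Queries are tested with findInterval arithmetic: O((q + r) log r)
# per iteration with no GRanges construction.

overlap_index <- function(reference, genome) {
  genome <- as_genome(genome)
  offset <- stats::setNames(cumsum(c(0, as.numeric(genome) + 1))[seq_along(genome)],
                            names(genome))
  merged <- GenomicRanges::reduce(reference, ignore.strand = TRUE)
  chroms <- as.character(GenomeInfoDb::seqnames(merged))
  rs <- offset[chroms] + GenomicRanges::start(merged) - 1  # 0-based global
  re <- offset[chroms] + GenomicRanges::end(merged)
  o <- order(rs)
  list(offset = offset, rs = rs[o], re = re[o])
}

# qs/qe are 0-based global coordinates; returns the number of queries with
# >= 1 shared base with some merged reference segment.
count_hits_global <- function(idx, qs, qe) {
  n <- length(idx$rs)
  if (n == 0L || length(qs) == 0L) return(0L)
  i <- findInterval(qs, idx$rs)
  hit_left <- i >= 1L & idx$re[pmax(i, 1L)] > qs
  hit_right <- i < n & idx$rs[pmin(i + 1L, n)] < qe
  sum(hit_left | hit_right)
}

count_overlapping_fast <- function(idx, chroms, start0, width) {
  qs <- idx$offset[chroms] + start0
  count_hits_global(idx, qs, qs + width)
}
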