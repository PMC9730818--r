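#' Feature-centered aggregation profile of DSBs
#'
#' Bins DSBs by the offset of their midpoint from the center of a chromatin
#' marker, over a fixed window (default 50 bins across a 20,000 bp window).
#' In \code{nearest} mode each DSB is assigned only to the feature whose
#' center is closest to the DSB midpoint on the same chromosome (ties go to
#' the leftmost feature), so each DSB lands in at most one bin. In \code{all}
#' mode a DSB is counted once for every feature whose center falls within the
#' window, the genome-wide all-feature variant.
#'
#' Midpoints and centers use the 0-based convention
#' \code{floor((start + end) / 2)}; an offset \code{d} falls in bin
#' \code{floor((d + window_bp/2) / bin_width)} when that index is in
#' \code{[0, n_bins)}. DSBs outside every window are dropped (and reported).
#'
#' @param dsbs \code{GRanges} of DSB regions
#' @param features nonempty \code{GRanges} of marker intervals
#' @param window_bp even window width in bp, divisible by \code{n_bins}
#' @param n_bins number of bins
#' @param mode \code{"nearest"} or \code{"all"}
#' @return an \code{aggregation_profile}: \code{bin_counts} (integer,
#'   length \code{n_bins}), bin edge offsets, mode and labels
#' @export
aggregate_profile <- function(dsbs, features, window_bp = 20000L, n_bins = 50L,
                              mode = c("nearest", "all")) {
  mode <- match.arg(mode)
  if (length(features) == 0) stop("features must be nonempty")
  if (window_bp <= 0 || window_bp %% 2 != 0 || window_bp %% n_bins != 0)
    stop("window_bp must be even and divisible by n_bins")
  bin_width <- window_bp / n_bins
  half <- window_bp / 2

  mid <- point0(dsbs)
  ctr <- point0(features)
  qchrom <- as.character(GenomeInfoDb::seqnames(dsbs))
  fchrom <- as.character(GenomeInfoDb::seqnames(features))

  offsets <- numeric(0)
  for (chrom in unique(qchrom)) {
    qi <- which(qchrom == chrom)
    fi <- which(fchrom == chrom)
    if (length(fi) == 0) next
    o <- order(ctr[fi], GenomicRanges::start(features)[fi])
    c_sorted <- ctr[fi][o]
    m <- mid[qi]
    if (mode == "nearest") {
      lo <- findInterval(m, c_sorted)
      lo_i <- pmax(lo, 1L)
      hi_i <- pmin(lo + 1L, length(c_sorted))
      d_lo <- abs(m - c_sorted[lo_i])
      d_hi <- abs(m - c_sorted[hi_i])
      use_lo <- lo >= 1L & (lo >= length(c_sorted) | d_lo <= d_hi)
      offsets <- c(offsets, m - ifelse(use_lo, c_sorted[lo_i], c_sorted[hi_i]))
    } else {
      a <- findInterval(m - half, c_sorted)        # centers <= m - half: excluded
      b <- findInterval(m + half, c_sorted)        # centers <= m + half: included
      reps <- pmax(b - a, 0L)
      if (sum(reps) > 0) {
        j <- sequence(reps, from = a + 1L)
        offsets <- c(offsets, rep(m, reps) - c_sorted[j])
      }
    }
  }

  bin <- floor((offsets + half) / bin_width)
  keep <- bin >= 0 & bin < n_bins
  counts <- tabulate(bin[keep] + 1L, nbins = n_bins)

  structure(list(
    bin_counts = as.integer(counts),
    n_bins = as.integer(n_bins),
    window_bp = as.integer(window_bp),
    bin_width = as.integer(bin_width),
    offset_edges = seq(-half, half, by = bin_width),
    mode = mode,
    n_query = length(dsbs),
    n_assigned = sum(keep),
    query = S4Vectors::metadata(dsbs)$label %||% "query",
    feature = S4Vectors::metadata(features)$label %||% "feature"),
    class = "aggregation_profile")
}

# 0-based representative point: midpoint for intervals, the BED-convention
# floor((start + end) / 2).
point0 <- function(x) {
  floor((GenomicRanges::start(x) - 1 + GenomicRanges::end(x)) / 2)
}

#' @export
print.aggregation_profile <- function(x, ...) {
  cat(sprintf("Aggregation profile (%s mode): %s around %s\n",
              x$mode, x$query, x$feature))
  cat(sprintf("  %d bins of %d bp over a %d bp window; %d of %d DSBs assigned\n",
              x$n_bins, x$bin_width, x$window_bp, x$n_assigned, x$n_query))
  peak <- which.max(x$bin_counts)
  cat(sprintf("  peak bin %d (offset %d..%d bp), count %d\n",
              peak - 1L, x$offset_edges[peak], x$offset_edges[peak + 1L],
              x$bin_counts[peak]))
  invisible(x)
}

#' @export
as.data.frame.aggregation_profile <- function(x, ...) {
  data.frame(bin = seq_len(x$n_bins) - 1L,
             offset_start = utils::head(x$offset_edges, -1),
             offset_end = utils::tail(x$offset_edges, -1),
             count = x$bin_counts)
}
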