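# Toy-data builders and independent brute-force oracles used across tests.

toy_genome <- function(lens = c(chrA = 10000, chrB = 5000)) genome(lens)

# GRanges from 0-based half-open triplets, optionally bound to a genome
gr0 <- function(chrom, start0, end0, genome = NULL, score = NULL) {
  x <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  if (!is.null(score)) x$score <- score
  if (!is.null(genome)) x <- bind_genome(x, genome)
  x
}

random_intervals <- function(g, n, max_len = 500) {
  g <- genome(unclass(g))
  chroms <- sample(names(g), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start0 <- floor(runif(n, 0, as.numeric(g[chroms]) - len + 1))
  gr0(chroms, start0, start0 + len, genome = g)
}

# all-pairs scan: number of query intervals sharing >= min_overlap bases with
# at least one reference interval
brute_count_overlapping <- function(query, reference, min_overlap = 1) {
  qc <- as.character(GenomicRanges::seqnames(query))
  rc <- as.character(GenomicRanges::seqnames(reference))
  qs <- GenomicRanges::start(query) - 1; qe <- GenomicRanges::end(query)
  rs <- GenomicRanges::start(reference) - 1; re <- GenomicRanges::end(reference)
  hit <- 0L
  for (i in seq_along(query)) {
    for (j in seq_along(reference)) {
      if (qc[i] == rc[j] &&
          min(qe[i], re[j]) - max(qs[i], rs[j]) >= min_overlap) {
        hit <- hit + 1L
        break
      }
    }
  }
  hit
}

# per-base accumulation of a stepwise track over one region
brute_mean_signal <- function(track, region, uncovered_as_zero = TRUE) {
  chrom <- as.character(GenomicRanges::seqnames(region))
  bases <- seq(GenomicRanges::start(region), GenomicRanges::end(region))
  val <- rep(NA_real_, length(bases))
  tc <- as.character(GenomicRanges::seqnames(track))
  for (j in seq_along(track)) {
    if (tc[j] != chrom) next
    sel <- bases >= GenomicRanges::start(track)[j] &
      bases <= GenomicRanges::end(track)[j]
    val[sel] <- track$score[j]
  }
  if (uncovered_as_zero) sum(val, na.rm = TRUE) / length(bases)
  else if (all(is.na(val))) NA_real_ else mean(val, na.rm = TRUE)
}

# elevated-over-regions track and seeded evaluation, via package internals
feature_track_for_test <- function(features, g, high = 5, low = 0.1) {
  breakmark:::feature_track(features, g, high = high, low = low)
}
with_seed_for_test <- function(seed, code) breakmark:::with_seed(seed, code)

random_track <- function(g, n_segments = 20, max_len = 400) {
  g <- genome(unclass(g))
  df <- do.call(rbind, lapply(names(g), function(chrom) {
    L <- as.numeric(g[chrom])
    k <- max(1, rpois(1, n_segments / length(g)))
    edges <- sort(sample.int(L - 1, min(2 * k, L - 2)))
    s0 <- edges[seq(1, length(edges) - 1, by = 2)]
    e0 <- pmin(edges[seq(2, length(edges), by = 2)], s0 + max_len)
    keep <- e0 > s0
    data.frame(chrom = chrom, s0 = s0[keep], e0 = e0[keep])
  }))
  gr0(df$chrom, df$s0, df$e0, genome = g,
      score = round(runif(nrow(df), -2, 5), 3))
}
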