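#' Split a condition's DSBs into shared and condition-unique sets
#'
#' A DSB is unique to condition \code{a} when it overlaps (by at least 1 bp)
#' no DSB of any other condition; the rest are shared.
#'
#' @param a \code{GRanges} of one condition's DSBs
#' @param others list of \code{GRanges} for the other conditions
#' @return list with elements \code{shared} and \code{unique}, both subsets of
#'   \code{a} (\code{length(shared) + length(unique) == length(a)})
#' @export
condition_sets <- function(a, others) {
  if (inherits(others, "GRanges")) others <- list(others)
  hit <- rep(FALSE, length(a))
  for (b in others) {
    check_same_genome(a, b)
    hit <- hit | GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0
  }
  list(shared = a[hit], unique = a[!hit])
}

#' Fraction of DSBs overlapping genes
#'
#' @param dsbs nonempty \code{GRanges}
#' @param genes \code{GRanges} of gene spans
#' @return real in [0, 1]: the genic fraction
#' @export
genic_fraction <- function(dsbs, genes) {
  if (length(dsbs) == 0) stop("genic_fraction is undefined for an empty DSB set")
  count_overlapping(dsbs, genes) / length(dsbs)
}

#' Per-chromosome DSB density
#'
#' @param dsbs \code{GRanges}
#' @param genome a \code{\link{genome}}; defaults to the genome bound to
#'   \code{dsbs}
#' @return named numeric vector: DSBs per Mb for every chromosome of the
#'   genome (0 for chromosomes with no DSBs)
#' @export
chromosome_density <- function(dsbs, genome = NULL) {
  genome <- if (is.null(genome)) genome_of(dsbs) else as_genome(genome)
  counts <- table(factor(as.character(GenomeInfoDb::seqnames(dsbs)),
                         levels = names(genome)))
  stats::setNames(1e6 * as.numeric(counts) / as.numeric(genome), names(genome))
}

#' Assign genes to size classes
#'
#' Classes in kb, half-open: [1, 100), [100, 300), [300, 800), [800, Inf).
#' Genes shorter than 1 kb are unclassified (\code{NA}).
#'
#' @param genes \code{GRanges}
#' @return factor along \code{genes} with levels
#'   \code{"1-100", "100-300", "300-800", ">800"}
#' @export
gene_size_class <- function(genes) {
  kb <- GenomicRanges::width(genes) / 1000
  cut(kb, breaks = c(1, 100, 300, 800, Inf), right = FALSE,
      labels = c("1-100", "100-300", "300-800", ">800"))
}

#' Hit counts and densities per gene size class
#'
#' For each gene size class, counts the hit intervals (DSBs or CTCF sites)
#' overlapping at least one gene of the class and divides by the class's
#' total gene length in Mb. A hit spanning genes of two classes counts once
#' in each class, so stacked class totals can exceed the number of hits.
#'
#' @param hits \code{GRanges} of DSBs or binding sites
#' @param genes \code{GRanges} of gene spans
#' @return data.frame with one row per size class: \code{size_class},
#'   \code{n_genes}, \code{total_gene_mb}, \code{n_hits}, \code{density_per_mb}
#'   (\code{NA} when a class has zero total length)
#' @export
gene_size_stats <- function(hits, genes) {
  check_same_genome(hits, genes)
  cls <- gene_size_class(genes)
  out <- lapply(levels(cls), function(lev) {
    g <- genes[!is.na(cls) & cls == lev]
    total_mb <- sum(GenomicRanges::width(g)) / 1e6
    n_hits <- if (length(g)) count_overlapping(hits, g) else 0L
    data.frame(size_class = lev, n_genes = length(g), total_gene_mb = total_mb,
               n_hits = n_hits,
               density_per_mb = if (total_mb > 0) n_hits / total_mb else NA_real_)
  })
  do.call(rbind, out)
}
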