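#' Define a genome as named chromosome lengths
#'
#' A genome here is simply the set of chromosome names and their lengths in
#' base pairs, as read from a \code{chrom.sizes} file. Interval sets are bound
#' to a genome through the \code{seqlengths} of their \code{GRanges}.
#'
#' @param lengths named numeric vector of chromosome lengths (bp), or a
#'   \code{Seqinfo} object.
#' @return named integer-valued numeric vector with class \code{"genome"}.
#' @examples
#' g <- genome(c(chr1 = 1e6, chr2 = 5e5))
#' genome_size(g)
#' @export
genome <- function(lengths) {
  if (methods::is(lengths, "Seqinfo")) {
    lengths <- stats::setNames(GenomeInfoDb::seqlengths(lengths),
                               GenomeInfoDb::seqnames(lengths))
  }
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("genome: chromosome names must be present and unique")
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths < 1) || any(lengths != floor(lengths)))
    stop("genome: lengths must be positive integers")
  structure(stats::setNames(lengths, nm), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d chromosome(s), %.3g Mb total\n",
              length(x), sum(x) / 1e6))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Total genome size in bp
#' @param g a \code{genome}
#' @export
genome_size <- function(g) sum(as_genome(g))

as_genome <- function(g) {
  if (inherits(g, "genome")) return(g)
  genome(g)
}

# Seqinfo construction is surprisingly costly (S4 method caching), so cache
# per distinct genome.
.si_cache <- new.env(parent = emptyenv())
genome_seqinfo <- function(g) {
  g <- as_genome(g)
  key <- paste(names(g), as.numeric(g), collapse = ";")
  si <- .si_cache[[key]]
  if (is.null(si)) {
    si <- GenomeInfoDb::Seqinfo(seqnames = names(g), seqlengths = as.integer(g))
    assign(key, si, envir = .si_cache)
  }
  si
}

#' Bind an interval set to a genome
#'
#' Attaches seqlengths and validates that every interval lies within
#' chromosome bounds.
#'
#' @param x a \code{GRanges}
#' @param g a \code{genome}
#' @return the same \code{GRanges} with seqinfo set.
#' @export
bind_genome <- function(x, g) {
  g <- as_genome(g)
  chroms <- as.character(GenomeInfoDb::seqnames(x))
  missing <- setdiff(unique(chroms), names(g))
  if (length(missing))
    stop("intervals on chromosomes absent from genome: ",
         paste(missing, collapse = ", "))
  over <- which(GenomicRanges::end(x) > g[chroms])
  if (length(over))
    stop(sprintf("interval %d (%s:%d-%d) exceeds chromosome length %d",
                 over[1], chroms[over[1]],
                 GenomicRanges::start(x)[over[1]] - 1L,
                 GenomicRanges::end(x)[over[1]],
                 as.integer(g[chroms[over[1]]])))
  GenomeInfoDb::seqlevels(x) <- names(g)
  GenomeInfoDb::seqinfo(x) <- genome_seqinfo(g)
  x
}

genome_of <- function(x) {
  sl <- GenomeInfoDb::seqlengths(x)
  if (any(is.na(sl)))
    stop("interval set is not bound to a genome (missing seqlengths)")
  genome(sl)
}

check_same_genome <- function(a, b) {
  ga <- GenomeInfoDb::seqlengths(a)
  gb <- GenomeInfoDb::seqlengths(b)
  shared <- intersect(names(ga), names(gb))
  if (!identical(ga[shared], gb[shared]) ||
      (!setequal(names(ga), names(gb)) && any(is.na(c(ga, gb)))))
    stop("interval sets are bound to different genomes")
  invisible(TRUE)
}

# Deterministic, order-independent substreams: a short name is folded into the
# master seed so each pipeline component draws from its own stream.
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}
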