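#' Read a chrom.sizes file
#'
#' Two-column TSV of chromosome name and length in bp.
#'
#' @param path file path
#' @return a \code{\link{genome}}
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome(stats::setNames(df$length, df$chrom))
}

#' Write a chrom.sizes file
#' @param g a \code{genome}
#' @param path output path
#' @export
write_chrom_sizes <- function(g, path) {
  g <- as_genome(g)
  utils::write.table(data.frame(names(g), format(as.numeric(g), scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# BED on disk is 0-based half-open; GRanges in memory is 1-based closed.
bed_to_granges <- function(df, genome = NULL, path = "<bed>") {
  if (any(bad <- !(df$start >= 0 & df$start < df$end))) {
    i <- which(bad)[1]
    stop(sprintf("%s line %d: invalid interval %s:%s-%s (need 0 <= start < end)",
                 path, i, df$chrom[i], df$start[i], df$end[i]))
  }
  gr <- GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end))
  if (!is.null(df$name)) names(gr) <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  if (!is.null(df$strand)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- s
  }
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    chroms <- as.character(GenomeInfoDb::seqnames(gr))
    bad <- !(chroms %in% names(genome)) | df$end > genome[chroms]
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("%s line %d: interval %s:%s-%s exceeds chromosome bounds",
                   path, i, df$chrom[i], df$start[i], df$end[i]))
    }
    gr <- bind_genome(gr, genome)
  }
  gr
}

#' Read a BED / narrowPeak file as a GRanges
#'
#' Accepts BED3, BED6 and ENCODE narrowPeak (BED6+4; the extra columns are
#' parsed into metadata columns but unused downstream). Coordinates are
#' converted from BED 0-based half-open to the 1-based closed convention of
#' \code{GRanges}; writers invert the conversion, so files round-trip.
#'
#' @param path file path
#' @param genome optional \code{\link{genome}}; when given, intervals beyond
#'   chromosome bounds are rejected with a line-numbered error.
#' @param label optional provenance label (e.g. condition name), stored in
#'   \code{metadata(x)$label}.
#' @return \code{GRanges}
#' @export
read_bed <- function(path, genome = NULL, label = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", colClasses = "character")
  ncol <- ncol(df)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")[seq_len(min(ncol, 10))]
  names(df)[seq_along(cols)] <- cols
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (!is.null(df$score)) df$score <- suppressWarnings(as.numeric(df$score))
  gr <- bed_to_granges(df, genome, path)
  for (extra in intersect(c("signalValue", "pValue", "qValue", "peak"), names(df)))
    S4Vectors::mcols(gr)[[extra]] <- suppressWarnings(as.numeric(df[[extra]]))
  if (anyDuplicated(paste(df$chrom, df$start, df$end)))
    warning(path, ": duplicated intervals retained")
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED3 plus name/score/strand columns when present.
#' @param x \code{GRanges}
#' @param path output path
#' @export
write_bed <- function(x, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x))
  nm <- names(x)
  has_score <- "score" %in% names(S4Vectors::mcols(x))
  st <- as.character(GenomicRanges::strand(x))
  if (!is.null(nm) || has_score || any(st != "*")) {
    df$name <- if (is.null(nm)) "." else nm
    df$score <- if (has_score) x$score else 0
    df$strand <- ifelse(st == "*", ".", st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file as a signal track
#'
#' Four columns (chrom, start, end, value), 0-based half-open. Returns a
#' \code{GRanges} with a \code{score} column; segments must not overlap within
#' a chromosome.
#'
#' @inheritParams read_bed
#' @return \code{GRanges} with numeric \code{score}
#' @export
read_bedgraph <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("chrom", "start", "end", "score"),
                          colClasses = c("character", "numeric", "numeric", "numeric"))
  gr <- bed_to_granges(df, genome, path)
  validate_track(gr)
}

#' Write a signal track as bedGraph
#' @param track \code{GRanges} with a \code{score} column
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    score = track$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_track <- function(track) {
  if (!"score" %in% names(S4Vectors::mcols(track)))
    stop("signal track needs a 'score' metadata column")
  if (any(!is.finite(track$score)))
    stop("signal track values must be finite")
  if (any(S4Vectors::selfmatch(track) != seq_along(track)) ||
      sum(S4Vectors::countQueryHits(
        GenomicRanges::findOverlaps(track, drop.self = TRUE))) > 0)
    stop("signal track segments overlap within a chromosome")
  sort(track)
}
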