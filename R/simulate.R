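#' Configuration for the synthetic DSB dataset generator
#'
#' Defines a toy genome with a gene catalog spanning four size classes,
#' epigenomic features (TSS, CTCF-like sites, H3K36me3-like blocks over an
#' "expressed" gene subset), per-feature signal tracks, a gene-density-driven
#' radial (GP-seq-like) score track, and three condition DSB sets (NT, DMSO,
#' APH) built from a uniform background plus planted components: a shared
#' spontaneous core reused across conditions, a fraction placed inside
#' H3K36me3-like blocks, and a fraction placed at a fixed offset on either
#' side of CTCF-like sites (the bimodal boundary pattern).
#'
#' Condition sizes default to 200/400/700, the observed 2111/3927/7002 DSB
#' catalog scaled to roughly one tenth so the full pipeline runs in seconds.
#'
#' @param n_chroms number of chromosomes
#' @param chrom_len_bp length of each chromosome in bp
#' @param genes_per_class gene counts for the 1-100, 100-300, 300-800 and
#'   >800 kb size classes
#' @param expressed_fraction fraction of genes carrying H3K36me3-like blocks
#' @param n_ctcf_intergenic intergenic CTCF-like sites in addition to one per
#'   TSS
#' @param dsb_counts named DSB counts per condition
#' @param shared_core_fraction fraction of NT DSBs reused verbatim in DMSO and
#'   APH
#' @param f_mark fraction of induced (non-core) DSBs planted inside
#'   H3K36me3-like blocks
#' @param f_ctcf fraction of induced DSBs planted at \code{ctcf_offset_bp}
#'   from a CTCF-like site center (random side)
#' @param ctcf_offset_bp planted midpoint offset from CTCF centers
#' @param dsb_len_meanlog,dsb_len_sdlog lognormal DSB length parameters
#'   (median 1 kb by default)
#' @param feature_signal,baseline_signal track values over/outside features
#' @param gpseq_bin_bp radial score bin width
#' @param seed master seed; every component draws from a named substream
#' @return a \code{sim_config} list
#' @export
sim_config <- function(n_chroms = 3L,
                       chrom_len_bp = 2e7,
                       genes_per_class = c(300L, 60L, 12L, 4L),
                       expressed_fraction = 0.4,
                       n_ctcf_intergenic = 100L,
                       dsb_counts = c(NT = 200L, DMSO = 400L, APH = 700L),
                       shared_core_fraction = 0.8,
                       f_mark = 0.5,
                       f_ctcf = 0.2,
                       ctcf_offset_bp = 2000L,
                       dsb_len_meanlog = log(1000),
                       dsb_len_sdlog = 0.5,
                       feature_signal = 5.0,
                       baseline_signal = 0.1,
                       gpseq_bin_bp = 1e6,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_chroms >= 1, chrom_len_bp >= 1e5,
            length(genes_per_class) == 4, all(genes_per_class >= 0),
            expressed_fraction >= 0, expressed_fraction <= 1,
            all(dsb_counts > 0), !is.null(names(dsb_counts)),
            shared_core_fraction >= 0, shared_core_fraction <= 1,
            f_mark >= 0, f_ctcf >= 0, f_mark + f_ctcf <= 1,
            ctcf_offset_bp >= 0, gpseq_bin_bp >= 1)
  structure(cfg, class = "sim_config")
}

#' Generate a complete synthetic dataset
#'
#' Deterministic given \code{config$seed}: all randomness flows from named
#' substreams of the master seed. Genes are placed without overlap
#' (longest-first assignment to the least-loaded chromosome, then random gap
#' spacing); every planted DSB's assignment (background / shared_core / mark /
#' ctcf) is recorded in the manifest so planted structure is recoverable.
#'
#' @param config a \code{\link{sim_config}}
#' @return list with \code{genome}, \code{genes} (GRanges with
#'   \code{gene_id}, \code{size_class}, \code{expressed}), \code{tss},
#'   \code{ctcf}, \code{h3k36me3}, \code{tracks} (named list of signal
#'   tracks), \code{gpseq} (radial score track), \code{dsbs} (named list of
#'   condition GRanges), \code{manifest} (data.frame), \code{config}
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  g <- genome(stats::setNames(rep(config$chrom_len_bp, config$n_chroms),
                              paste0("chr", seq_len(config$n_chroms))))
  si <- genome_seqinfo(g)

  genes <- with_seed(substream_seed(config$seed, "genes"),
                     place_genes(g, config$genes_per_class))
  genes$expressed <- with_seed(
    substream_seed(config$seed, "expression"),
    seq_along(genes) %in% sample(length(genes),
                                 round(config$expressed_fraction * length(genes))))

  # TSS = gene 5' end (width-1 intervals)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  tss_pos <- ifelse(plus, GenomicRanges::start(genes), GenomicRanges::end(genes))
  tss <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::IRanges(tss_pos, width = 1), seqinfo = si)
  S4Vectors::metadata(tss)$label <- "TSS"

  # H3K36me3-like blocks tile expressed gene bodies
  h3k36me3 <- GenomicRanges::granges(genes[genes$expressed])
  GenomicRanges::strand(h3k36me3) <- "*"
  S4Vectors::metadata(h3k36me3)$label <- "H3K36me3"

  ctcf <- with_seed(substream_seed(config$seed, "ctcf"),
                    place_ctcf(g, genes, tss, config$n_ctcf_intergenic))

  tracks <- lapply(list(TSS = tss, CTCF = ctcf, H3K36me3 = h3k36me3),
                   feature_track, genome = g,
                   high = config$feature_signal, low = config$baseline_signal)
  gpseq <- gene_density_track(g, genes, config$gpseq_bin_bp)

  core_n <- round(config$shared_core_fraction * config$dsb_counts[[1]])
  conditions <- names(config$dsb_counts)
  dsbs <- list()
  manifest <- list()
  core <- NULL
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    n <- config$dsb_counts[[ci]]
    res <- with_seed(
      substream_seed(config$seed, paste0("dsb_", cond)),
      build_condition(g, n, cond, core = if (ci > 1) core else NULL,
                      h3k36me3 = h3k36me3, ctcf = ctcf, config = config,
                      planted = ci > 1))
    if (ci == 1) core <- res$dsbs[seq_len(min(core_n, n))]
    dsbs[[cond]] <- res$dsbs
    manifest[[cond]] <- res$manifest
  }

  list(genome = g, genes = genes, tss = tss, ctcf = ctcf, h3k36me3 = h3k36me3,
       tracks = tracks, gpseq = gpseq, dsbs = dsbs,
       manifest = do.call(rbind, manifest), config = config)
}

# Draw gene lengths log-uniformly within their class bounds (kb); real gene
# catalogs are heavily skewed toward short genes.
class_bounds_kb <- rbind(c(1, 100), c(100, 300), c(300, 800), c(800, 1600))

place_genes <- function(g, genes_per_class) {
  lens <- unlist(lapply(seq_len(4), function(k) {
    n <- genes_per_class[k]
    if (n == 0) return(numeric(0))
    round(exp(stats::runif(n, log(class_bounds_kb[k, 1] * 1000),
                           log(class_bounds_kb[k, 2] * 1000 - 1))))
  }))
  if (length(lens) == 0) stop("no genes requested")
  # longest-first to the least-loaded chromosome, then random in-chromosome
  # order with stick-broken gaps. Gap weights grow exponentially along the
  # chromosome so gene density declines from one end to the other, giving the
  # 1-Mb radial score track a genuine gene-density gradient.
  ord <- order(-lens)
  load <- stats::setNames(rep(0, length(g)), names(g))
  chrom_of <- character(length(lens))
  for (i in ord) {
    c_min <- names(which.min(load))
    chrom_of[i] <- c_min
    load[c_min] <- load[c_min] + lens[i]
  }
  if (any(load > as.numeric(g)))
    stop("gene catalog exceeds chromosome capacity; enlarge the genome")
  si <- genome_seqinfo(g)
  pieces <- lapply(names(g), function(chrom) {
    idx <- which(chrom_of == chrom)
    if (!length(idx)) return(NULL)
    idx <- idx[sample.int(length(idx))]
    free <- as.numeric(g[chrom]) - sum(lens[idx])
    gaps <- stats::rexp(length(idx) + 1) * exp(seq(0, 6, length.out = length(idx) + 1))
    gaps <- floor(gaps / sum(gaps) * free)
    start0 <- cumsum(gaps[seq_along(idx)]) + cumsum(c(0, lens[idx][-length(idx)]))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1,
                                                   width = lens[idx]),
                           strand = sample(c("+", "-"), length(idx), TRUE),
                           gene_index = idx, seqinfo = si)
  })
  out <- do.call(c, pieces[!vapply(pieces, is.null, logical(1))])
  out <- out[order(out$gene_index)]
  out$gene_index <- NULL
  out$gene_id <- sprintf("gene%04d", seq_along(out))
  names(out) <- out$gene_id
  out$size_class <- gene_size_class(out)
  out
}

place_ctcf <- function(g, genes, tss, n_intergenic, site_bp = 200L) {
  centers0 <- GenomicRanges::start(tss) - 1
  chroms <- as.character(GenomeInfoDb::seqnames(tss))
  if (n_intergenic > 0) {
    L <- as.numeric(g)
    extra_chrom <- sample(names(g), n_intergenic * 20, TRUE, prob = L / sum(L))
    pos0 <- floor(stats::runif(length(extra_chrom), 0, g[extra_chrom]))
    cand <- GenomicRanges::GRanges(extra_chrom, IRanges::IRanges(pos0 + 1, width = 1))
    keep <- GenomicRanges::countOverlaps(cand, genes, ignore.strand = TRUE) == 0
    take <- utils::head(which(keep), n_intergenic)
    centers0 <- c(centers0, pos0[take])
    chroms <- c(chroms, extra_chrom[take])
  }
  half <- site_bp %/% 2L
  start0 <- pmax(0, pmin(centers0 - half, as.numeric(g[chroms]) - site_bp))
  out <- GenomicRanges::GRanges(chroms,
                                IRanges::IRanges(start0 + 1, width = site_bp),
                                seqinfo = genome_seqinfo(g))
  S4Vectors::metadata(out)$label <- "CTCF"
  sort(out)
}

# Elevated value over feature intervals, baseline elsewhere (full coverage).
feature_track <- function(features, genome, high = 5, low = 0.1) {
  genome <- as_genome(genome)
  si <- genome_seqinfo(genome)
  red <- GenomicRanges::reduce(GenomicRanges::granges(features),
                               ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(red) <- names(genome)
  GenomeInfoDb::seqinfo(red) <- si
  gap <- GenomicRanges::gaps(red)
  gap <- gap[as.character(GenomicRanges::strand(gap)) == "*"]
  red$score <- rep(high, length(red))
  gap$score <- rep(low, length(gap))
  sort(c(red, gap))
}

# Radial (GP-seq-like) score: per fixed-width bin, the genic base fraction,
# rescaled to (0, 1]; gene-dense bins score nearer the nuclear center.
gene_density_track <- function(g, genes, bin_bp = 1e6) {
  bins <- GenomicRanges::tileGenome(genome_seqinfo(g), tilewidth = bin_bp,
                                    cut.last.tile.in.chrom = TRUE)
  cov <- GenomicRanges::coverage(GenomicRanges::reduce(
    GenomicRanges::granges(genes), ignore.strand = TRUE))
  frac <- GenomicRanges::binnedAverage(bins, cov, "score")$score
  bins$score <- round(0.05 + 0.95 * frac, 6)
  S4Vectors::metadata(bins)$label <- "GPseq"
  bins
}

dsb_lengths <- function(n, config) {
  pmax(100, round(stats::rlnorm(n, config$dsb_len_meanlog, config$dsb_len_sdlog)))
}

uniform_dsbs <- function(g, n, lens) {
  L <- as.numeric(g)
  chroms <- sample(names(g), n, TRUE, prob = L / sum(L))
  start0 <- draw_starts(as.numeric(g[chroms]), lens)
  GenomicRanges::GRanges(chroms, IRanges::IRanges(start0 + 1, width = lens),
                         seqinfo = genome_seqinfo(g))
}

# The first (untreated) condition is pure uniform background: planted mark /
# CTCF components model drug-induced breaks only.
build_condition <- function(g, n, cond, core, h3k36me3, ctcf, config,
                            planted = TRUE) {
  si <- genome_seqinfo(g)
  parts <- list()
  assign <- list()
  n_core <- if (is.null(core)) 0L else length(core)
  if (n_core > 0) {
    parts$core <- GenomicRanges::granges(core)
    assign$core <- rep("shared_core", n_core)
  }
  n_induced <- n - n_core
  n_mark <- if (planted) round(config$f_mark * n_induced) else 0L
  n_ctcf <- if (planted) round(config$f_ctcf * n_induced) else 0L
  n_bg <- n_induced - n_mark - n_ctcf

  if (n_mark > 0) {
    lens <- dsb_lengths(n_mark, config)
    # uniform over mark bases: block chosen proportional to its length
    block <- sample(length(h3k36me3), n_mark, replace = TRUE,
                    prob = GenomicRanges::width(h3k36me3))
    bs0 <- GenomicRanges::start(h3k36me3)[block] - 1
    bw <- GenomicRanges::width(h3k36me3)[block]
    off <- floor(stats::runif(n_mark, 0, pmax(bw - lens, 0) + 1))
    chroms <- as.character(GenomeInfoDb::seqnames(h3k36me3))[block]
    start0 <- pmin(bs0 + off, as.numeric(g[chroms]) - lens)
    parts$mark <- GenomicRanges::GRanges(
      chroms, IRanges::IRanges(start0 + 1, width = lens), seqinfo = si)
    assign$mark <- rep("mark", n_mark)
  }
  if (n_ctcf > 0) {
    lens <- dsb_lengths(n_ctcf, config)
    site <- sample(length(ctcf), n_ctcf, replace = TRUE)
    side <- sample(c(-1, 1), n_ctcf, replace = TRUE)
    mid0 <- point0(ctcf)[site] + side * config$ctcf_offset_bp
    chroms <- as.character(GenomeInfoDb::seqnames(ctcf))[site]
    start0 <- mid0 - floor(lens / 2)
    start0 <- pmax(0, pmin(start0, as.numeric(g[chroms]) - lens))
    parts$ctcf <- GenomicRanges::GRanges(
      chroms, IRanges::IRanges(start0 + 1, width = lens), seqinfo = si)
    assign$ctcf <- rep("ctcf", n_ctcf)
  }
  if (n_bg > 0) {
    parts$bg <- uniform_dsbs(g, n_bg, dsb_lengths(n_bg, config))
    assign$bg <- rep("background", n_bg)
  }
  dsbs <- do.call(c, unname(parts))
  assignment <- unlist(assign, use.names = FALSE)
  dsbs$assignment <- assignment
  names(dsbs) <- sprintf("%s_dsb%04d", cond, seq_along(dsbs))
  S4Vectors::metadata(dsbs)$label <- cond
  list(dsbs = dsbs,
       manifest = data.frame(condition = cond, index = seq_along(dsbs),
                             chrom = as.character(GenomeInfoDb::seqnames(dsbs)),
                             start = GenomicRanges::start(dsbs) - 1L,
                             end = GenomicRanges::end(dsbs),
                             assignment = assignment))
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact plain-text formats the analysis readers accept:
#' \code{chrom.sizes}, BED files for genes, features and per-condition DSBs,
#' bedGraph signal and radial score tracks, and a JSON manifest of planted
#' assignments.
#'
#' @param bundle output of \code{\link{simulate_dataset}}
#' @param outdir output directory (created if needed)
#' @return \code{outdir}, invisibly
#' @export
write_dataset <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_chrom_sizes(bundle$genome, p("genome.chrom.sizes"))
  write_bed(bundle$genes, p("genes.bed"))
  write_bed(bundle$tss, p("tss.bed"))
  write_bed(bundle$ctcf, p("ctcf.bed"))
  write_bed(bundle$h3k36me3, p("h3k36me3.bed"))
  for (nm in names(bundle$tracks))
    write_bedgraph(bundle$tracks[[nm]], p(sprintf("signal_%s.bedGraph", nm)))
  write_bedgraph(bundle$gpseq, p("gpseq.bedGraph"))
  for (cond in names(bundle$dsbs))
    write_bed(bundle$dsbs[[cond]], p(sprintf("dsb_%s.bed", cond)))
  jsonlite::write_json(bundle$manifest, p("manifest.json"), dataframe = "rows")
  invisible(outdir)
}
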