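sim_small <- function(seed = 1, ...) {
  simulate_dataset(sim_config(seed = seed, ...))
}

test_that("generated DSB counts, genes and features match the configuration", {
  b <- sim_small(seed = 3)
  cfg <- b$config
  expect_identical(vapply(b$dsbs, length, integer(1)),
                   vapply(cfg$dsb_counts, as.integer, integer(1)))
  expect_identical(length(b$genes), sum(cfg$genes_per_class))
  expect_identical(as.integer(table(b$genes$size_class)),
                   as.integer(cfg$genes_per_class))
  expect_identical(length(b$h3k36me3),
                   as.integer(round(cfg$expressed_fraction * length(b$genes))))
  expect_identical(length(b$tss), length(b$genes))
  # genes do not overlap within a chromosome
  expect_identical(sum(GenomicRanges::countOverlaps(b$genes, b$genes,
                                                    ignore.strand = TRUE)),
                   length(b$genes))
})

test_that("generation is fully deterministic given the seed", {
  a <- sim_small(seed = 11)
  b <- sim_small(seed = 11)
  expect_identical(a$manifest, b$manifest)
  expect_identical(GenomicRanges::start(a$genes), GenomicRanges::start(b$genes))
  expect_identical(a$gpseq$score, b$gpseq$score)
  c <- sim_small(seed = 12)
  expect_false(identical(a$manifest, c$manifest))
})

test_that("the shared spontaneous core reappears in the treated conditions", {
  b <- sim_small(seed = 5)
  frac <- b$config$shared_core_fraction
  sets_dmso <- condition_sets(b$dsbs$NT, list(b$dsbs$DMSO))
  sets_aph <- condition_sets(b$dsbs$NT, list(b$dsbs$APH))
  expect_gte(length(sets_dmso$shared) / length(b$dsbs$NT), frac)
  expect_gte(length(sets_aph$shared) / length(b$dsbs$NT), frac)
  # the manifest records the planted assignment of every DSB
  expect_identical(nrow(b$manifest), sum(vapply(b$dsbs, length, integer(1))))
  tab <- table(b$manifest$condition, b$manifest$assignment)
  expect_identical(as.integer(tab["DMSO", "shared_core"]),
                   as.integer(round(frac * length(b$dsbs$NT))))
  expect_identical(as.integer(tab["NT", "background"]), length(b$dsbs$NT))
})

test_that("mark-planted DSBs overlap the mark and drive enrichment", {
  b <- sim_small(seed = 9)
  m <- b$manifest[b$manifest$condition == "APH", ]
  planted <- b$dsbs$APH[m$assignment == "mark"]
  expect_identical(count_overlapping(planted, b$h3k36me3), length(planted))
  res <- permutation_enrichment(b$dsbs$APH, b$h3k36me3, n_iterations = 500,
                                seed = 2)
  expect_equal(res$p_value, 0)
})

test_that("CTCF-planted DSBs produce the bifurcated profile at +-2000 bp", {
  b <- sim_small(seed = 21)
  prof <- aggregate_profile(b$dsbs$APH, b$ctcf, mode = "nearest")
  top2 <- order(-prof$bin_counts)[1:2] - 1L
  expect_setequal(top2, c(20L, 30L))   # (+-2000 + 10000) / 400
})

test_that("signal tracks are elevated exactly over their features", {
  b <- sim_small(seed = 2)
  tr <- b$tracks$H3K36me3
  expect_setequal(unique(tr$score),
                  c(b$config$feature_signal, b$config$baseline_signal))
  inside <- mean_signal_over_region(tr, b$h3k36me3[1:10])
  expect_true(all(inside == b$config$feature_signal))
  # track covers the whole genome
  expect_equal(sum(GenomicRanges::width(tr)), genome_size(b$genome))
})

test_that("the radial score track follows local gene density", {
  b <- sim_small(seed = 2)
  genic <- GenomicRanges::reduce(GenomicRanges::granges(b$genes),
                                 ignore.strand = TRUE)
  genic$score <- rep(1, length(genic))
  frac <- mean_signal_over_region(genic, b$gpseq)   # genic fraction per bin
  expect_gt(cor(frac, b$gpseq$score), 0.999)
  mrk <- b$manifest[b$manifest$condition == "APH", "assignment"] == "mark"
  r <- radial_scores(b$dsbs$APH, b$gpseq)
  mw <- wilcox.test(r$dsb_scores[mrk], r$background_scores,
                    alternative = "greater")
  expect_lt(mw$p.value, 0.001)
})

test_that("infeasible gene catalogs are a configuration error", {
  cfg <- sim_config(n_chroms = 1, chrom_len_bp = 2e6,
                    genes_per_class = c(5L, 2L, 1L, 4L), seed = 1)
  expect_error(simulate_dataset(cfg), "capacity")
})

test_that("written datasets read back into equivalent objects", {
  b <- sim_small(seed = 13)
  dir <- withr::local_tempdir()
  write_dataset(b, dir)
  g <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  expect_identical(names(g), names(b$genome))
  dmso <- read_bed(file.path(dir, "dsb_DMSO.bed"), genome = g)
  expect_identical(GenomicRanges::start(dmso), GenomicRanges::start(b$dsbs$DMSO))
  gp <- read_bedgraph(file.path(dir, "gpseq.bedGraph"), genome = g)
  expect_equal(gp$score, b$gpseq$score)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_identical(nrow(man), nrow(b$manifest))
})
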