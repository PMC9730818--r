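#!/usr/bin/env Rscript
# Random-forest classification of condition-unique DSBs against matched null
# regions (same chromosome and length, sampled outside the full DSB catalog),
# in both feature-signal and feature-distance modes, 700 trees, out-of-bag
# evaluation.

suppressMessages(library(breakmark))
dir.create("results", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

d <- "results/dataset"
g <- read_chrom_sizes(file.path(d, "genome.chrom.sizes"))
tracks <- sapply(c("H3K36me3", "CTCF", "TSS"), function(f)
  read_bedgraph(file.path(d, sprintf("signal_%s.bedGraph", f)), g),
  simplify = FALSE)
feature_sets <- list(
  H3K36me3 = read_bed(file.path(d, "h3k36me3.bed"), g),
  CTCF = read_bed(file.path(d, "ctcf.bed"), g),
  TSS = read_bed(file.path(d, "tss.bed"), g))
dsbs <- sapply(c("NT", "DMSO", "APH"), function(cond)
  read_bed(file.path(d, sprintf("dsb_%s.bed", cond)), g, label = cond),
  simplify = FALSE)
all_dsbs <- do.call(c, unname(lapply(dsbs, GenomicRanges::granges)))

reports <- list()
for (cond in names(dsbs)) {
  others <- dsbs[setdiff(names(dsbs), cond)]
  uniq <- condition_sets(dsbs[[cond]], unname(others))$unique
  if (length(uniq) < 20) next
  nulls <- sample_matched_nulls(uniq, exclude = all_dsbs, seed = seed)
  for (mode in c("signal", "distance")) {
    fm <- if (mode == "signal")
      build_feature_matrix(uniq, nulls, tracks = tracks, mode = "signal")
    else
      build_feature_matrix(uniq, nulls, feature_sets = feature_sets,
                           mode = "distance")
    rep <- train_evaluate(fm, n_trees = 700, seed = seed)
    message(sprintf("-- %s-unique (%d regions), %s mode", cond, length(uniq), mode))
    print(rep)
    reports[[paste(cond, mode, sep = "_")]] <- list(
      condition = cond, mode = mode, n_regions = length(uniq),
      auroc = rep$auroc, pr_auc = rep$pr_auc,
      class_errors = as.list(rep$class_errors),
      importance = apply(rep$importance, 2, function(v)
        as.list(stats::setNames(v, rownames(rep$importance)))))
  }
}
jsonlite::write_json(reports, "results/classifier_reports.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/classifier_reports.json")
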