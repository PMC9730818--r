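#!/usr/bin/env Rscript
# Feature-centered aggregation profiles: DSB counts in 50 bins across a
# 20 kb window around each marker, nearest-marker and all-marker modes.
# The CTCF-like profile of the treated conditions should be bimodal at
# +-2 kb (the planted boundary pattern).

suppressMessages(library(breakmark))
dir.create("results", showWarnings = FALSE)

d <- "results/dataset"
g <- read_chrom_sizes(file.path(d, "genome.chrom.sizes"))
features <- list(
  H3K36me3 = read_bed(file.path(d, "h3k36me3.bed"), g, label = "H3K36me3"),
  CTCF = read_bed(file.path(d, "ctcf.bed"), g, label = "CTCF"),
  TSS = read_bed(file.path(d, "tss.bed"), g, label = "TSS"))

out <- list()
for (cond in c("NT", "DMSO", "APH")) {
  dsbs <- read_bed(file.path(d, sprintf("dsb_%s.bed", cond)), g, label = cond)
  for (feat in names(features)) {
    for (mode in c("nearest", "all")) {
      prof <- aggregate_profile(dsbs, features[[feat]], mode = mode)
      df <- as.data.frame(prof)
      df$condition <- cond; df$feature <- feat; df$mode <- mode
      out[[paste(cond, feat, mode)]] <- df
      if (mode == "nearest") print(prof)
    }
  }
}
write.table(do.call(rbind, out), "results/profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/profiles.tsv")
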