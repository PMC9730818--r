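#!/usr/bin/env Rscript
# Permutation overlap-enrichment of each condition's DSBs against each
# chromatin feature (1000 per-chromosome shuffles). Expectation from the
# planted structure: DMSO and APH enriched in H3K36me3-like blocks; NT is
# uniform background and should not be.

suppressMessages(library(breakmark))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

d <- "results/dataset"
g <- read_chrom_sizes(file.path(d, "genome.chrom.sizes"))
features <- list(
  H3K36me3 = read_bed(file.path(d, "h3k36me3.bed"), g, label = "H3K36me3"),
  CTCF = read_bed(file.path(d, "ctcf.bed"), g, label = "CTCF"),
  TSS = read_bed(file.path(d, "tss.bed"), g, label = "TSS"))

rows <- list()
for (cond in c("NT", "DMSO", "APH")) {
  dsbs <- read_bed(file.path(d, sprintf("dsb_%s.bed", cond)), g, label = cond)
  for (feat in names(features)) {
    res <- permutation_enrichment(dsbs, features[[feat]],
                                  n_iterations = 1000, seed = seed)
    print(res)
    rows[[paste(cond, feat)]] <- as.data.frame(res)
  }
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/enrichment.tsv")
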