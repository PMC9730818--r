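#!/usr/bin/env Rscript
# Radial-position analysis: per-DSB GP-seq-like scores against the genomic
# background of 1-Mb bin scores. Treated conditions, whose planted component
# sits in gene bodies, should shift toward gene-dense (high-score) bins.

suppressMessages(library(breakmark))
dir.create("results", showWarnings = FALSE)

d <- "results/dataset"
g <- read_chrom_sizes(file.path(d, "genome.chrom.sizes"))
gpseq <- read_bedgraph(file.path(d, "gpseq.bedGraph"), g)

rows <- list()
for (cond in c("NT", "DMSO", "APH")) {
  dsbs <- read_bed(file.path(d, sprintf("dsb_%s.bed", cond)), g, label = cond)
  r <- radial_scores(dsbs, gpseq)
  print(r)
  mw <- suppressWarnings(wilcox.test(r$dsb_scores, r$background_scores,
                                     alternative = "greater"))
  message(sprintf("  one-sided Mann-Whitney vs background: p = %.3g", mw$p.value))
  df <- as.data.frame(r)
  df$condition <- cond
  rows[[cond]] <- df
}
write.table(do.call(rbind, rows), "results/radial_histograms.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/radial_histograms.tsv")
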