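#!/usr/bin/env Rscript
# Condition set algebra and gene-context statistics: shared/unique DSBs per
# condition, genic fraction of the unique sets, per-chromosome density, and
# gene-size-class densities of DSBs and CTCF-like sites.

suppressMessages(library(breakmark))
dir.create("results", showWarnings = FALSE)

d <- "results/dataset"
g <- read_chrom_sizes(file.path(d, "genome.chrom.sizes"))
genes <- read_bed(file.path(d, "genes.bed"), g, label = "genes")
ctcf <- read_bed(file.path(d, "ctcf.bed"), g, label = "CTCF")
dsbs <- sapply(c("NT", "DMSO", "APH"), function(cond)
  read_bed(file.path(d, sprintf("dsb_%s.bed", cond)), g, label = cond),
  simplify = FALSE)

sets_rows <- list(); size_rows <- list()
for (cond in names(dsbs)) {
  others <- dsbs[setdiff(names(dsbs), cond)]
  sets <- condition_sets(dsbs[[cond]], unname(others))
  gf <- genic_fraction(sets$unique, genes)
  message(sprintf("%s: %d DSBs, %d shared, %d unique (genic fraction of unique: %.2f)",
                  cond, length(dsbs[[cond]]), length(sets$shared),
                  length(sets$unique), gf))
  sets_rows[[cond]] <- data.frame(
    condition = cond, n = length(dsbs[[cond]]), shared = length(sets$shared),
    unique = length(sets$unique), genic_fraction_unique = gf)
  st <- gene_size_stats(dsbs[[cond]], genes)
  st$condition <- cond; st$hits <- "DSB"
  size_rows[[cond]] <- st
}
st_ctcf <- gene_size_stats(ctcf, genes)
st_ctcf$condition <- "features"; st_ctcf$hits <- "CTCF"
size_rows$ctcf <- st_ctcf

dens <- sapply(dsbs, chromosome_density)
message("per-chromosome density (per Mb):")
print(round(dens, 2))

write.table(do.call(rbind, sets_rows), "results/condition_sets.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, size_rows), "results/gene_size_stats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(chrom = rownames(dens), dens),
            "results/chromosome_density.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/condition_sets.tsv, gene_size_stats.tsv, chromosome_density.tsv")
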