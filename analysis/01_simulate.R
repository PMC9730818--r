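#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a 3 x 20 Mb genome with a gene catalog
# in four size classes, TSS / CTCF-like / H3K36me3-like features with signal
# tracks, a gene-density radial score track, and NT / DMSO / APH DSB sets with
# planted structure. Writes plain-text inputs for the downstream stages.

suppressMessages(library(breakmark))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- sim_config(seed = seed)
bundle <- simulate_dataset(cfg)

outdir <- "results/dataset"
write_dataset(bundle, outdir)

message(sprintf("genome: %d chromosomes, %.0f Mb", length(bundle$genome),
                genome_size(bundle$genome) / 1e6))
message(sprintf("genes: %d (%s per size class)", length(bundle$genes),
                paste(table(bundle$genes$size_class), collapse = "/")))
message(sprintf("DSBs: %s",
                paste(sprintf("%s=%d", names(bundle$dsbs),
                              vapply(bundle$dsbs, length, integer(1))),
                      collapse = ", ")))
message(sprintf("planted assignments:\n%s",
                paste(capture.output(table(bundle$manifest$condition,
                                           bundle$manifest$assignment)),
                      collapse = "\n")))
message("dataset written to ", outdir)
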