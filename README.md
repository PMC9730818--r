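# breakmark

Tools for placing DNA double-strand breaks (DSBs) in their epigenomic
context. The package targets the analysis setting of Break-seq-style DSB
mapping experiments: interval sets of breaks called in untreated cells (NT),
in vehicle-treated cells (DMSO), and under mild replication stress
(aphidicolin, APH), to be related to chromatin features such as H3K36me3
peaks, CTCF binding sites, TSSs, and radial-position (GP-seq) scores.

It is written for computational biologists who have per-condition DSB BED
files, feature peak files, signal tracks and a chromosome-sizes table, and
want the following analyses as tested, seeded, scriptable functions:

* **Permutation overlap enrichment** — is the number of DSBs overlapping a
  feature (≥ 1 bp) higher than expected? The null re-places every DSB
  uniformly at random within its own chromosome, keeping its length
  (shuffleBed semantics). With observed count `k_obs` and shuffled counts
  `k_1 … k_N`,

  `p = #{i : k_i ≥ k_obs} / N`

  reported as `p < 1/N` when no shuffle reaches the observed count.
* **Feature-centered aggregation profiles** — DSB counts in 50 bins across a
  20 kb window around the nearest marker (or around every marker in range),
  the classic metagene view that exposes bimodal DSB placement around CTCF
  sites.
* **Condition set algebra and gene context** — shared/condition-unique DSBs,
  genic fraction, per-chromosome density per Mb, and hit densities stratified
  by gene size class (1–100, 100–300, 300–800, > 800 kb).
* **Radial scoring** — per-DSB base-pair-weighted mean of 1-Mb GP-seq scores
  versus the genomic background distribution.
* **Matched-null classification** — random-forest discrimination of real DSBs
  from random regions with matched chromosome and length distributions, using
  either mean feature signal over the region or distance to the nearest
  feature, with out-of-bag AUROC, PR-AUC, per-class errors and both
  permutation and impurity variable importance (700 trees).
* **A synthetic-data generator** — a toy genome with genes in four size
  classes, expressed-gene H3K36me3-like blocks, CTCF-like sites, signal
  tracks, a gene-density-driven radial score track, and three DSB conditions
  with planted, manifest-recorded structure, so the entire pipeline can be
  exercised and validated without any external download.

Intervals are `GenomicRanges::GRanges` throughout; files are plain-text
BED / narrowPeak / bedGraph / chrom.sizes, read and written with 0-based
half-open coordinates on disk.

## Worked example

```r
library(breakmark)

bundle <- simulate_dataset(sim_config(seed = 7))

permutation_enrichment(bundle$dsbs$DMSO, bundle$h3k36me3, seed = 11)
#> Permutation overlap enrichment: DMSO vs H3K36me3
#>   observed overlaps : 166
#>   null mean (range) : 79.2 (55-103) over 1000 iterations
#>   p < 0.001   [seed 11]

aggregate_profile(bundle$dsbs$APH, bundle$ctcf)
#> Aggregation profile (nearest mode): APH around CTCF
#>   50 bins of 400 bp over a 20000 bp window; 177 of 700 DSBs assigned
#>   peak bin 30 (offset 2000..2400 bp), count 55

radial_scores(bundle$dsbs$APH, bundle$gpseq)
#> Radial (GP-seq) score summary: APH
#>   700 scored DSBs (0 unscored), mean score 0.579 vs genomic mean 0.488
```

Reading the output: 166 of 400 DMSO DSBs touch an H3K36me3-like block while
random placement produces at most 103 — enrichment with an empirical p below
the 1/1000 resolution of the test. The profile's peak at bin 30 (offset
+2000 bp; its mirror peak sits at bin 20) is the planted bimodal flanking of
CTCF-like sites. The APH radial-score mean exceeding the genomic bin average
reflects breaks concentrated in gene-dense, nucleus-central regions.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
dataset and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1      # dataset + planted-assignment manifest
Rscript analysis/02_enrichment.R 1    # permutation tests, all conditions x features
Rscript analysis/03_profiles.R        # 50-bin aggregation profiles
Rscript analysis/04_context.R         # shared/unique sets, densities, gene-size stats
Rscript analysis/05_radial.R          # GP-seq-style score histograms
Rscript analysis/06_classify.R 1      # matched-null random forests
```

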