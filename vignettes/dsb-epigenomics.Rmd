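---
title: "Methods: associating DNA double-strand breaks with epigenomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: associating DNA double-strand breaks with epigenomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakmark)
```

# The problem

Break-seq-style experiments map DNA double-strand breaks (DSBs) genome-wide
under different conditions — untreated (NT), vehicle (DMSO), and mild
replication stress (aphidicolin, APH). The analytical questions downstream
are all positional: are breaks enriched in transcribed chromatin (H3K36me3),
how do they distribute around architectural features (CTCF sites, TSSs),
do they favor small, densely packed genes over large ones, do they sit in
gene-dense regions near the nuclear center (high GP-seq score), and can
chromatin features alone predict where breaks occur? This package implements
those analyses as seeded, tested functions over `GRanges` interval sets.

# The permutation enrichment test

The core statistic is the number of DSB intervals sharing at least one base
with at least one feature interval; each DSB counts at most once regardless
of how many features it touches. Coordinates are BED-convention 0-based
half-open, so an interval ending exactly where a feature starts does not
overlap it. Strand is ignored everywhere: break ends and the downloaded peak
formats carry no meaningful orientation.

The null model re-places each DSB uniformly at random within its own
chromosome, preserving its length, with no exclusion zones; shuffled
intervals may overlap each other and their original positions. This is the
most conservative reading of a per-chromosome count-preserving shuffle: it
conditions on the observed chromosome occupancy (so inter-chromosomal
density differences cannot masquerade as feature enrichment) while assuming
nothing about mappability or assembly gaps. With observed count
$k_{obs}$ and $N$ shuffled counts $k_i$,

$$p = \frac{\#\{i : k_i \ge k_{obs}\}}{N},$$

a one-sided enrichment p-value with no +1 correction; ties count against
enrichment, and an exceedance count of zero is reported as the bound
$p < 1/N$. $N$ defaults to 1000. Each iteration draws from its own
substream of the master seed (a fold of the seed with the iteration label),
so the result is independent of iteration order and reproducible
per-iteration.

Depletion is deliberately not tested: the analysis questions are all of the
enrichment form, and a two-sided variant would halve the resolution of the
reported bound.

## Numerical and performance choices

The permutation loop never materializes shuffled `GRanges`. Feature
intervals are merged per chromosome and laid on a single numeric axis (one
spacer base between chromosomes prevents merging across the boundary);
each iteration draws the start vector and counts hits with `findInterval`
arithmetic. A test asserts exact agreement between this path and
`count_overlapping()` on random inputs. A 1000-iteration test of 400 DSBs
against ~150 merged blocks runs in well under a second.

# Aggregation profiles

Profiles count DSBs in 50 bins of 400 bp across a 20,000 bp window centered
on chromatin markers. A DSB is represented by its midpoint
$\lfloor (start+end)/2 \rfloor$ and a feature by the same center formula;
offset $d$ falls in bin $\lfloor (d + w/2) / (w/n) \rfloor$ kept when in
$[0, n)$. Using midpoints keeps every DSB in exactly one bin, so the profile
total is interpretable as "DSBs assigned". In `nearest` mode only the
closest marker on the same chromosome receives the DSB (ties broken to the
leftmost marker, a deterministic convention); in `all` mode a DSB increments
one bin for every marker whose center lies within the window — the
genome-wide variant that counts DSB–feature pairs in dense regions. Nearest
mode is the default because it matches the per-marker reading of the
profile; both modes are reported by the analysis driver.

# Condition sets and gene context

A DSB of condition A is *unique* when it overlaps (≥ 1 bp) no DSB of any
other condition; shared and unique subsets partition the input exactly.
Genic fraction is the overlap-count fraction against gene spans and is
invariant to merging overlapping genes. Gene size classes use half-open
kilobase bounds [1,100), [100,300), [300,800), [800,∞); genes under 1 kb are
left unclassified. A hit interval spanning genes of two classes is counted
once in each class — per-class tallies are independent, so stacked totals
can exceed the number of hits — and per-class density divides by the class's
summed gene length in Mb. Where a gene catalog carries multiple isoforms the
caller should supply one span per gene (e.g. the longest isoform); the
package does not collapse isoforms itself.

# Radial (GP-seq) scoring

Each DSB receives the base-pair-weighted mean of the scores of the 1-Mb bins
it overlaps — "tallied, averaged" — with uncovered bases excluded from the
divisor; an unweighted per-bin mean is available as a sensitivity option.
DSBs on chromosomes absent from the score table are counted as *unscored*
and reported, never silently dropped. The genomic background is the multiset
of all bin scores; both distributions are histogrammed on shared,
equal-width edges over the pooled range (20 bins by default; the figure this
mirrors does not state its edges, so they are configurable).

# Matched-null classification

Null regions are sampled one per DSB with the same chromosome and length,
uniformly, rejection-resampled (cap 1000 attempts, then an error naming the
region) until they overlap nothing in the exclusion set — normally the full
DSB catalog across conditions. Feature matrices come in two variants:
*signal*, the mean of a track over the region under the "mean0" convention
(uncovered bases count as zero — break regions routinely extend past peak
coverage; the covered-bases-only mean and a summed variant are options), and
*distance*, the edge-to-edge gap to the nearest feature interval, with
regions on chromosomes lacking the feature encoded as the chromosome length:
a genome-scale sentinel that preserves "far" ordering without introducing
missing values.

The classifier is a 700-tree random forest with the default classification
`mtry` ($\sqrt{p}$), evaluated out-of-bag: AUROC, PR-AUC (step-function
integration of the precision–recall curve over score thresholds, ties
collapsed), per-class error rates, and both permutation
(mean-decrease-accuracy) and impurity (mean-decrease-Gini) importance. One
caveat discovered and documented in the tests: out-of-bag votes are slightly
anti-correlated with the held-out row's label, so on *label-free* data OOB
AUROC is biased away from 0.5, severely so when features are near-binary.
The `holdout` option (stratified train/test split) is the unbiased
evaluation and is what the chance-level test uses; OOB remains the default
because it matches the ensemble idiom for real, informative data and uses
every region.

# The synthetic dataset

`simulate_dataset()` builds everything the pipeline consumes, determined
entirely by one seed with named substreams per component (genes, expression,
CTCF placement, each condition's DSBs), so no component's draw disturbs
another's.

**Genome and genes.** Three chromosomes of 20 Mb. The gene catalog holds
300/60/12/4 genes in the four size classes, lengths log-uniform within class
bounds (real catalogs skew short). The stated class counts imply ~28 Mb of
gene length, so the genome is sized at 60 Mb to give a human-like ~45–50%
genic fraction with room for non-overlapping placement. Genes go
longest-first to the least-loaded chromosome, then are laid out in random
order with exponentially growing stick-broken gaps: gene density declines
~e^6-fold along each chromosome, emulating the gene-dense versus gene-desert
contrast that makes radial position predictable from local gene density.

**Features.** TSSs are gene 5′ ends (width 1). H3K36me3-like blocks cover
the bodies of a 40% "expressed" gene subset. CTCF-like sites are 200 bp
intervals at every TSS plus 100 random intergenic positions. Signal tracks
are stepwise-constant: 5.0 over the feature, 0.1 elsewhere. The radial score
per 1-Mb bin is the bin's genic base fraction rescaled to (0, 1] — a direct
gene-density proxy.

**DSB conditions.** NT (200 breaks) is uniform background: spontaneous
breaks carry no planted feature preference. DMSO (400) and APH (700) reuse
80% of NT verbatim (the shared spontaneous core) and build their induced
remainder as 50% placed uniformly over H3K36me3-like bases, 20% centered at
±2000 bp from a random CTCF-like site (the bimodal boundary pattern;
±2000 bp puts the two modes in bins 20 and 30 of the default profile), and
30% uniform background. Break lengths are lognormal with 1 kb median.
Condition sizes are the observed 2111/3927/7002 catalog scaled to ~1/10 so
the full pipeline runs in seconds. A manifest records every break's planted
assignment, making recall of planted structure measurable.

**What the generator does not emulate.** No sequence (no motifs, GC,
mappability), no assembly gaps, no replication timing, no expression levels
beyond the binary expressed flag, no correlated peak co-occurrence beyond
the TSS/CTCF coupling, and independent uniform placement within categories
rather than hotspot clustering. Tests passing on this generator therefore
validate the statistical machinery — calibration, planted-effect recovery,
geometric conventions — not robustness to the biases of real sequencing
data (which the shuffle null deliberately does not model either).

# Test and acceptance problem sizes

The suite checks the interval algebra against brute-force per-base scans
(100 random instances), shuffle uniformity by exact enumeration (length-2
interval on a length-4 chromosome, 3000 seeds, chi-square at α = 0.01),
permutation p against exact enumeration (3 placements, 3000 iterations,
binomial 99% CI), type-I calibration over 200 null datasets (no mark
planting; 400 iterations each), planted recovery over 100 datasets (feature
covering 5% of a 60 Mb genome, half the breaks inside, 1000 iterations),
and classifier sanity over 20 seeded forests. These sizes were chosen so
the statistical assertions have the power their tolerance bands assume
while the whole suite stays fast; all are set in the tests, not in the
package.

# Known limitations

* The shuffle null conditions only on chromosome and length; GC-,
  mappability- or gap-aware nulls are out of scope.
* No multiple-testing correction across features — tests are reported
  per feature, matching the per-feature analysis this package reproduces.
* narrowPeak columns beyond the first six are parsed but unused (no
  summit-based centering).
* bigWig input is not read directly; convert to bedGraph first. The package
  is deliberately free of binary-format dependencies.
* The classifier offers no hyperparameter search and no alternative
  learners; it reproduces one analysis contract, not a benchmark.
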