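---
title: "Methods: transferring ChIP-seq signal across cell types with accessibility similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transferring ChIP-seq signal across cell types with accessibility similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibind)
```

## The prediction problem

Given reference cell types with both chromatin accessibility (DNase-seq or
ATAC-seq peak calls) and ChIP-seq peaks for one or more targets, and a query
cellular context with accessibility alone, `epibind` estimates the
probability that each 200 bp genome bin carries a ChIP-seq peak for each
target in the query. The model's central assumption is that accessibility is
informative of epigenetic events: where the query's local chromatin landscape
resembles a reference cell's, that reference's ChIP-seq peaks are good
evidence for the query. Two consequences follow directly from the design:

* **Binary signal.** All inputs are reduced to presence/absence of a peak per
  bin. This discards quantitative signal but removes sensitivity to
  sequencing depth, antibody quality, and other technical scale factors, and
  makes assays of different kinds directly composable.
* **Bounded sensitivity.** Features come from reference peaks, so the model
  predicts exactly 0 in any bin where no reference cell has any peak. The
  unique-peak-fraction analysis (`unique_peak_curve()`) quantifies this
  ceiling: the fraction of a held-out cell type's peaks unseen in a pooled
  reference set shrinks as the pool grows.

## Dataset assembly

`read_peak_file()` parses BED3+/narrowPeak (0-based half-open; narrowPeak
statistics columns are irrelevant to binarization and ignored).
`bin_and_binarize()` marks a bin positive on any ≥ 1 bp overlap — peak
callers already apply significance thresholds, so no minimum-overlap rule is
imposed. Replicates are merged by `consensus_merge()`: 1 replicate passes
through, 2 are unioned, 3 require ≥ 2 supporting replicates, and ≥ 4 require
≥ 25% of replicates with a ceiling, `ceiling(0.25 n)`. The three small-n rules
are deliberately hard-coded rather than derived from the percentage formula
(which would give a 1-of-3 rule instead of 2-of-3).

`build_dataset()` keeps only bins with at least one peak in any track (the
*region index*) and partitions them by chromosome: chr7 → validation,
chr8/chr9 → test, optionally chr22 → train-validation (used only by early
stopping), the remaining autosomes → training. Sex and mitochondrial
chromosomes (a configurable name list, default chrX/chrY/chrM) are excluded.
When early stopping is disabled the train-validation chromosome folds into
the training set; whether to hold it out anyway is controlled entirely by
`split_config()`, since either convention is defensible.

## The chromatin accessibility similarity vector

For query and reference tracks $a^q, a^k$ and bin $i$, windows of
$|r_z| \in \{1, 5, 19, 59\}$ bins are centered on $i$ and each reduced to its
exclusive ring $r_z \setminus r_{z-1}$ (sizes 1, 4, 14, 40), so each entry
reflects a distinct distance band out to roughly 12 kb:

$$\mathrm{CASV}_p[z] = \frac{\sum_{g \in r_z \setminus r_{z-1}} a^q_g a^k_g}
 {|r_z| - |r_{z-1}|}, \qquad
 \mathrm{CASV}_n[z] = \frac{\sum_{g \in r_z \setminus r_{z-1}}
 \mathbf{1}[a^q_g = a^k_g]}{|r_z| - |r_{z-1}|}$$

with the final vector $[\mathrm{CASV}_p \,\|\, \mathrm{CASV}_n]$ — positive
part first. Peaks are sparse, so $\mathrm{CASV}_n$ is dominated by shared
absence; $\mathrm{CASV}_p$ isolates shared *presence*, which marks shared
regulatory regions. Numerical choices:

* **Chromosome edges.** Bins beyond the chromosome are treated as 0 in both
  tracks: they count as agreement in $\mathrm{CASV}_n$ and contribute nothing
  to $\mathrm{CASV}_p$, and the denominators stay at the full ring size. This
  keeps the vector's length and scale constant at every position, which the
  dense layers require; the first and last ~29 bins of a chromosome are
  mildly biased toward agreement as a result.
* **Third-ring denominator.** The positive part's third entry uses
  $|r_2| - |r_1| = 14$, following the pattern of every other ring.
* **Multi-assay extension.** When the query has histone-mark ChIP-seq in
  addition to accessibility, `multi_assay_casv()` computes a CASV per assay
  and concatenates blocks in a fixed assay order (accessibility first),
  giving $8m$ features per reference cell for $m$ assays.

The implementation computes all positions of a chromosome at once from
cumulative sums; tests verify it against an independent ring-enumeration
oracle at every position of a toy chromosome, including both edges.

## Network, features, and rotation training

Features for reference cell $k$ at bin $i$ are
$x_i^k = [F_i^k \,\|\, \mathrm{CASV}(i, a^q, a^k)]$, where $F_i^k$ holds the
cell's binarized peaks for the model targets it has measured. Channel $k$
applies two tanh layers ($\lfloor d/2\rfloor$, then
$\max(1, \lfloor d/4\rfloor)$ units for input width $d$, so 4 and 2 for the
minimal width of 9); the concatenated channel outputs pass through a single
dense layer to one logit per target, then a sigmoid. Combining by
concatenation + dense layer is the minimal faithful reading of "channel
outputs combined into a final output layer", and it also absorbs
heterogeneous target availability across cells: a channel's $F_i^k$ only
contains what $k$ measured.

Training rotates the label source: for each region in a (shuffled) training
list and each cell $k$ in dataset order, one instance is formed with labels
$y = F_i^k$ (restricted to the predicted targets) and features from *all*
channels — including $k$'s own, whose CASV is then the identity similarity of
its accessibility with itself. The label cell is deliberately not masked from
its own channel: seeing its own labels behind a maximal similarity vector is
what teaches the network to up-weight similar cells. This is label leakage by
design, and it is why evaluation must be on held-out chromosomes and a query
never used as a reference.

The loss is the numerically stable sigmoid cross-entropy
$\max(\hat y, 0) - \hat y y + \log(1 + e^{-|\hat y|})$ (equal to the textbook
logistic loss to $10^{-9}$ over $|\hat y| \le 20$, verified in tests, but
immune to overflow). Optimization uses Adam at step size $10^{-3}$ with
symmetric uniform fan-in initialization — the de-facto defaults for small
dense networks, chosen once and seeded. Batches hold 64 instances; training
runs between `min_batches` (default 800) and `max_batches` (default 5000).
Gradients are analytic (plain backpropagation in matrix form) and are checked
against central finite differences to $10^{-5}$ in the test suite.

## Imbalance-aware sampling

With several targets in one model, peak counts differ by orders of magnitude
across labels. For label $l$ with positive count $c_l$,
$\mathrm{IRLbl}(l) = \max_{l'} c_{l'} / c_l$ and $\mathrm{meanIR}$ is its mean
over labels. Every label with $\mathrm{IRLbl}(l) > \mathrm{meanIR}$ (strictly;
boundary labels are not resampled) receives
$k_l = \lfloor 10\, (\mathrm{IRLbl}(l)/\mathrm{meanIR})\, c_l \rfloor$ extra
instances drawn uniformly with replacement from its positives. The summary is
computed once on the original training set, with all qualifying labels
quantified simultaneously — not iteratively rebalanced. Oversampling is
verified to strictly decrease every qualifying label's recomputed IRLbl.
Single-target models instead undersample negatives, without replacement, to
10× the positive count. A region counts as positive for a label if *any*
reference cell has a peak there — the instance unit for sampling is the
region, and the rotation then crosses sampled regions with all label cells.

## Early stopping

Every 200 batches (`valid_interval`), the loss is evaluated on 1000 instances
(`valid_sample`) drawn from the train-validation chromosome through the same
sampling scheme as training. Training halts when the best loss has not
improved by more than `min_delta` (default 0) for `patience` (default 5)
consecutive evaluations — the validation loss may rise before reaching its
minimum, which the patience absorbs. The "weighted mean" of the validation
loss is implemented as a plain mean (uniform weights), there being no
defensible alternative weighting at this granularity.

## Evaluation

* `auprc()` — step-wise (non-interpolated) area under precision-recall with
  ties grouped; a constant scorer gets the prevalence.
* `partial_auc()` — trapezoidal ROC area clipped to FPR ∈ [0, 0.05], McClish
  standardized as $\tfrac12 (1 + (p\mathrm{AUC} - p\mathrm{AUC}_{rand}) /
  (p\mathrm{AUC}_{perf} - p\mathrm{AUC}_{rand}))$, matching the convention of
  the common Python implementation and of pROC's corrected partial AUC
  (cross-checked in tests). Note this maps a perfect classifier to 1 and a
  random one to 0.5; the worst possible ranking lands slightly below 0.49,
  not at 0, because the standardization is affine in the raw area.
* `select_test_regions()` — evaluation is restricted to bins that overlap a
  ChIP-seq peak for the evaluated target or an accessibility peak from a cell
  type measuring that target. Outside that set the model predicts 0 by
  construction, and including such trivially negative bins would inflate
  ranking metrics.
* `jaccard()` (binary track overlap) and `shapley_over_assays()` (exact
  Shapley values over assay subsets, for attributing performance to the
  assays included in the similarity vector) support downstream analyses.

## The synthetic data generator

`generate_fixture()` emulates, at desk scale, the structure the model
exploits: a backbone of bins accessible in every cell (rate 0.10) plus
cell-specific accessible bins (rate 0.05); target peaks conditioned on
accessibility (P(peak | accessible) = 0.6 vs 0.02 otherwise, so peaks
co-occur with accessibility and are correlated between cells through the
shared backbone); and a query whose true accessibility is a per-bin mixture
of the references' (default 0.6 weight on the first cell). Bernoulli flip
noise (rate 0.05) perturbs only the *observed* accessibility tracks — assay
noise — while peaks and the query's ground truth derive from the pre-noise
accessibility. Defaults are 10 chromosomes × 2000 bins (20,000 bins, so the
standard chr7/chr8–9 split applies) and 5 reference cells. Rates were chosen
once to make accessibility informative but imperfect: with these settings a
single-target model reliably beats both the prevalence baseline and the
constant-similarity ablation within 1500 batches, while perfect prediction is
impossible because the query's truth is an independent draw rather than a
copy of any reference.

What the generator does *not* emulate: peak length structure (every peak is
one isolated bin-level event; real peaks span bins and cluster), distance
effects such as enhancer–promoter correlation, mappability artifacts, or
quantitative signal. Passing tests on fixtures therefore demonstrates the
mechanism — similarity-weighted transfer of reference peaks — not genome-scale
performance.

## Ablation

`casv_mode = "identity"` replaces every similarity vector with the constant
identity CASV (shared-peak part 0, agreement part 1). The model then sees
only reference peak counts, with no way to tell which references resemble the
query locally, and its held-out auPRC drops accordingly — this contrast is
asserted in the acceptance tests and recomputed by `scripts/acceptance.R`.

## Problem sizes and determinism

The test suite runs the end-to-end experiment on the default 20,000-bin,
5-cell fixture with 1500 training batches (about 15 s), oracle comparisons on
200-bin toy chromosomes, and $10^5$-pair loss checks; the whole suite takes
a couple of minutes. Every stochastic component — fixture generation, weight
initialization, shuffling, sampling, validation draws — flows from a single
integer seed per run, and identical seeds reproduce loss histories and
fixture file trees byte for byte.

## Known limitations

* Sensitivity is capped by reference coverage (see above); rare, cell-type
  selective events absent from all references are invisible.
* Training-time label leakage through the label cell's own channel is
  intentional; reported metrics are only meaningful on held-out chromosomes
  and query contexts never used for training labels.
* The dense network is small and CPU-bound by design; very large models
  (hundreds of targets × many cells) would benefit from a compiled backend,
  which this implementation does not provide.
* Multi-label models require every training cell to carry every predicted
  target as a label source; cells may still contribute heterogeneous feature
  sets through their channels.
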