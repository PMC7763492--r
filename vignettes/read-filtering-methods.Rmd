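---
title: "Singleton filtering and cross-platform TCR repertoire comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Singleton filtering and cross-platform TCR repertoire comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repfilter)
```

## The problem

A T-cell receptor (TCR) repertoire is summarised as a table of clonotypes:
unique CDR3 amino-acid sequences, each with a supporting-read count, V/D/J
gene calls and per-clonotype mapping-quality features. Two assays produce
such tables from the same RNA: targeted immune-repertoire sequencing
(IR-seq), which amplifies TCR transcripts and yields millions of TCR reads
per sample, and bulk RNA-seq, whose TCR reads are a sparse by-catch of a
few hundred reads. Deep amplification also multiplies the opportunities
for sequencing and mapping error: a single erroneous read creates a novel
"clonotype" indistinguishable, by sequence alone, from a rare true clone.

`repfilter` implements a quality-control and comparison pipeline for such
paired data. Its premise, and the recommendation it encodes, is that
*clonotypes supported by a single read should be removed*: singletons are
the stratum where artifacts concentrate, and they can be diagnosed as such
by their mapping-quality distribution.

## Filtering model

Filtering is expressed as a single inclusive-keep convention: a threshold
`min_reads` keeps every clonotype with at least that many supporting
reads. `min_reads = 2` removes singletons; `min_reads = 3` additionally
removes doubletons. This avoids the off-by-one ambiguity of phrases such
as "removing clonotypes with less than two reads". Because every singleton
carries exactly one read, singleton removal obeys an exact identity:
post-filter reads = total reads − singleton clonotypes. The packaged
31-sample multiple-myeloma cohort summary satisfies this identity row by
row, and `cohort_range_report()` reproduces its cohort-wide pre- and
post-filter read ranges from that arithmetic alone.

Every filter call returns a conservation report (clonotypes and reads
removed, singleton fractions). Filtering is idempotent and monotone in the
threshold; the test suite asserts both, together with exact conservation,
on a thousand random tables.

## Quality diagnostics

Clonotypes are stratified by supporting-read count (counts at or above a
cap, default 10, pool into one top bin). Each clonotype contributes one
scalar quality score — the mean of its quality feature vector — and the
singleton stratum is compared against every other stratum with two-sample
Kolmogorov–Smirnov tests, Benjamini–Hochberg adjusted across the family
(`ks_singleton_vs_groups()`). Adjacent multi-read strata are compared the
same way (`ks_adjacent_groups()`): if only the singleton stratum is
contaminated, those comparisons should be quiet.

For a clonotype-level view, the quality feature vectors are centred,
scaled to unit variance (the features have heterogeneous scales; scaling
keeps no single feature dominant) and projected onto their first two
principal components. A two-cluster partition is then fit with k-means
(k = 2, seed-controlled) on the PC scores, and the cluster with the lower
mean scalar quality is labelled *low*. The labelling rule makes the output
invariant to cluster-index permutation. We read the published description
of this step — "k-nearest neighbour clustering with k = 2" — as a
two-cluster partition; k-NN is a supervised classifier and cannot, by
itself, define clusters, so 2-means on the first two PCs is the minimal
faithful implementation of "clustering with k = 2 to determine the low-
and high-quality clonotypes".

Degenerate inputs are handled explicitly: constant features are dropped
with a warning (PCA aborts if none remain), a single usable feature pins
PC2 at zero with a flag, and a point cloud collapsing to one location
refuses to cluster.

## Overlap, gene usage, clonal expansion

Clonotype identity defaults to the CDR3 amino-acid sequence alone, because
cross-platform sharing is defined at the amino-acid level (several
nucleotide variants translate to one clonotype; ingest merges them,
summing reads and averaging quality by read weight). A V/J-qualified key
is available via the `key` argument throughout.

* `shared_across_samples()` counts, per clonotype key, the samples
  containing it. `paired_shared()` intersects one matched IR/RNA pair.
* `retention_under_filter()` filters both sides at the same threshold and
  reports the eliminated fraction of the raw overlap.
* `shared_frequency_correlation()` recomputes relative frequencies on the
  post-filter totals (each condition is internally consistent that way)
  and correlates the pooled (IR, RNA) frequency points of all shared
  clonotypes across pairs; per-pair correlations are also returned. The
  pooled-clonotype view is the default because one pooled cloud is what a
  before/after scatter comparison shows; Pearson is the default and
  Spearman is a flag, since neither is canonical for this comparison.
* `relative_usage()` counts clonotypes (not reads) per V/D/J gene and
  scales by the sample's largest gene count, so the top gene is exactly 1.
  `compare_usage()` runs per-gene Welch t-tests between platforms on the
  union gene set, with absent genes contributing usage 0 — in sparse
  RNA-seq, absence is data, and excluding it would bias platform means
  upward. Raw p-values are thresholded by default (BH optional), and
  zero-variance-on-both-sides genes are flagged degenerate rather than
  silently mishandled.
* `top_n_proportion()` ranks clonotypes by read count (ties broken
  lexicographically on the key, for determinism) and sums the top-N
  relative frequency; `compare_expansion()` Welch-compares per-sample
  proportions between conditions. Post-filter proportions use the
  post-filter denominator. Samples retaining fewer than N clonotypes are
  excluded via `min_clonotype_guard()` — their proportion is trivially 1
  and would distort the comparison.

## Downsampling

`downsample_counts()` thins a sample to `floor(p × total_reads)` reads by
drawing without replacement from the read pool labelled by clonotype — a
multivariate hypergeometric draw, equivalent in distribution to
subsampling the read file and re-tabulating, given that each read supports
one clonotype. `recovery_curve()` evaluates a grid of proportions
(default 1%–60%); with `nested = TRUE` the subsets are prefixes of one
random read permutation, so unique and shared clonotype counts are
non-decreasing in depth *exactly*, not merely in expectation. Independent
draws per depth remain available. `recovery_significance()` Welch-compares
shared-clonotype counts between adjacent depths across replicate seeds.

In the pipeline the RNA side of a recovery curve is singleton-filtered
first. That choice follows the package's own recommendation — the
reference set should be the reliable clonotypes — and it is what gives the
curve its saturation behaviour: multi-read RNA clonotypes sit at
frequencies deep IR-seq captures even at 1% depth, so the shared count is
flat in depth. Against a raw RNA reference the curve instead keeps rising
with depth, because chance singleton captures of rare clones are only
reachable at high IR depth.

## The synthetic-data generator

`sim_config()` fixes the study conditions the pipeline is tested under;
the defaults are one latent repertoire sequenced at `ir_depth = 5×10⁶`
IR reads and `rna_depth = 500` RNA reads, with per-read artifact
probability `error_rate = 0.05`.

* **Clone frequencies.** `n_true_clones = 10⁵` latent clones with sizes
  from a power law of density exponent 2 (rank–frequency slope ≈ −1),
  truncated at `freq_cap = 10⁵` so the top clonal fraction stays a few
  percent. The defaults give ~10⁵ observed multi-read clonotypes and
  ~3.5×10⁵ total observed clonotypes per deep sample — the order seen in
  real deep IR-seq — and populate every support stratum from 1 up to the
  pooling cap, which the KS family needs. The clone count trades off
  against tail mass: far fewer clones would empty the low-support strata,
  far more would starve each of reads.
* **Artifacts.** Each read independently becomes an artifact with
  probability ε, spawning a novel clonotype whose CDR3 is a point
  substitution of its source clone's CDR3. Candidate CDR3s colliding with
  an existing key are re-drawn; because the single-substitution
  neighbourhood of a short CDR3 is small, persistent collisions escalate
  to an additional substitution. Every artifact clonotype is therefore a
  novel key — a singleton — which encodes the modelling assumption that
  recurrent errors are handled upstream by the aligner's error correction
  and what remains is the unrepeatable residue.
* **Quality.** Each clonotype has a latent quality mean — N(60, 5) for
  true clones, a degraded N(35, 8) for artifacts, truncated at zero — and
  its reads scatter around that mean with `read_noise_sd = 2`. The
  feature vector is the mean/min/max/sd of the per-read draws (sd of a
  single read is 0). Placing the quality signal at the clonotype level
  matters: it makes the quality distribution of multi-read strata nearly
  identical, as observed, whereas purely per-read quality would shrink
  each stratum's variance as 1/√(count) and make every stratum
  distinguishable at these sample sizes.
* **Ground truth.** Every generated sample carries a truth table
  (artifact flag, true frequency, source clone), so filter recall and
  precision, quality-cluster recovery and pool recovery are measurable,
  not asserted.

What the generator does *not* emulate: VDJ recombination (CDR3s are
random strings with a C...F motif and an 8–20 length law peaked at 14),
molecular barcodes/UMIs, PCR amplification bias, and recurrent
(non-singleton) error modes. Passing tests therefore demonstrate the
pipeline's behaviour under the stated statistical structure, not under
every failure mode of real libraries.

## Problem sizes and numerical choices

The test suite runs the statistical recovery properties at the default
conditions with 100 replicate seeds for the KS significance rates and 20
for the ground-truth recovery, correlation-limit and saturation checks;
unit tests use a reduced configuration (2×10³ clones, 5×10⁴ reads) chosen
to exercise every code path quickly. The acceptance script uses 20 and 10
replicates respectively. Oracle-equivalence checks (KS statistic against a
double-loop ECDF supremum, Pearson against the covariance formula, Welch
against the closed form) are asserted to 10⁻¹⁰ on two hundred random
inputs each.

Seeds propagate from one master seed per run: repertoire, per-platform
sequencing, k-means initialisation and every downsampling draw derive
from it, so any result can be reproduced bit for bit. Ties in top-N
ranking break lexicographically; hypergeometric thinning uses exact
integer targets `floor(p × N)`; empty post-filter samples are legal
inputs downstream and are either handled (zero shared counts) or excluded
with a warning (expansion comparisons).

## Known limitations

* Clonotype identity ignores the nucleotide sequence; convergent
  recombination is invisible at this granularity.
* The Welch comparison of gene usage treats samples as exchangeable
  replicates; patient-level covariates are out of scope.
* The low/high quality partition assumes two latent quality populations;
  with no artifacts present the split is arbitrary (the KS diagnostics,
  not the clustering, should drive the filtering decision there).
* Aggregate cohort-level singleton percentages depend on deduplicated
  union denominators that per-sample summaries cannot reconstruct; the
  package reports per-sample fractions instead.
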