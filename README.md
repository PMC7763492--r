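# repfilter

Read filtering and cross-platform comparison for T-cell receptor (TCR)
repertoires.

## The problem

TCR repertoires are profiled either by targeted immune-repertoire
sequencing (IR-seq), which yields millions of TCR reads per sample, or as
the sparse TCR by-catch of bulk RNA-seq (typically a few hundred reads).
Deep amplification multiplies sequencing/mapping errors, and every
erroneous read can masquerade as a novel clonotype (a unique CDR3
amino-acid sequence). Clonotypes supported by a **single read** are the
stratum where these artifacts concentrate; carrying them forward inflates
repertoire diversity and corrupts cross-platform comparisons.

`repfilter` is for analysts with paired (or single-platform) clonotype
tables who need principled quality control before repertoire statistics.
It implements:

* **Singleton filtering** — keep clonotypes with `read_count >= min_reads`
  (default 2), with exact conservation reports. Under singleton removal,
  post-filter reads = total reads − singleton clonotypes, exactly.
* **Quality diagnostics** — stratify clonotypes by read support, compare
  the singleton stratum's mapping-quality distribution against every other
  stratum with two-sample Kolmogorov–Smirnov tests
  (Benjamini–Hochberg-adjusted), and classify clonotypes low/high quality
  by k-means (k = 2) on the first two principal components of their
  quality features.
* **Overlap statistics** — clonotypes shared across samples or between
  matched platforms; retention of the overlap under filtering; Pearson
  correlation of shared-clonotype frequencies (recomputed on post-filter
  totals), pooled across pairs.
* **Gene usage** — relative V/D/J usage per sample,
  `p(gene) = clonotype count / max clonotype count in category`, compared
  between platforms with per-gene Welch t-tests (absent genes count 0).
* **Clonal expansion** — cumulative frequency of the top-N clonotypes
  before/after filtering, Welch-compared across samples.
* **Downsampling** — multivariate-hypergeometric thinning of read counts
  and nested shared-clonotype recovery curves over a depth grid, with
  Welch tests between adjacent depths.
* **A synthetic generator** — paired deep-IR/sparse-RNA samples from one
  heavy-tailed latent repertoire, with a per-read artifact process and
  ground-truth labels, so every stage is testable without external data.

The package also ships a per-sample sequencing summary of a 31-sample
multiple-myeloma cohort (paired IR-seq and bulk RNA-seq) used by the
cohort-level operations.

Tables in, tibbles out: clonotype tables are ordinary tibbles
(AIRR-style and MiXCR-style TSVs are read via a configurable column map),
every function composes with the pipe, results have `tidy()`/`glance()`
and `autoplot()`/`plot_*()` methods.

## Worked example

```r
library(repfilter)

cfg  <- sim_config(n_true_clones = 5000, ir_depth = 200000,
                   rna_depth = 400, seed = 42)
pair <- simulate_pair(cfg, sample_id = "MM_sim")

singleton_stats(dplyr::bind_rows(pair$ir, pair$rna))
#>   sample_id platform total_reads unique_clonotypes singleton_clonotypes
#> 1 MM_sim    IR            200000             15097                10224
#> 2 MM_sim    RNA              400               200                  165
#>   singleton_clonotype_fraction singleton_read_fraction
#> 1                        0.677                  0.0511
#> 2                        0.825                  0.412
```

Two thirds of the deep sample's clonotypes are singletons, yet they carry
only 5% of its reads; the sparse RNA sample is singleton-heavy on both
scales. Filtering both sides removes most of the raw overlap — which is
the point: what survives is reliable.

```r
retention_under_filter(pair$ir, pair$rna, min_reads = 2)
#>   min_reads shared_before shared_after eliminated_fraction
#> 1         2           185           35               0.811

groups <- group_by_support(pair$ir, cap = 10)
ks_singleton_vs_groups(groups)
#>   group_a group_b   n_a   n_b statistic p_value p_adjusted significant
#> 1 1       2       10224   254     0.937       0          0 TRUE
#> 2 1       3       10224   369     0.941       0          0 TRUE
#> ...
```

The singleton stratum's quality distribution is drastically different
from every multi-read stratum (KS statistic ≈ 0.94), while adjacent
multi-read strata are indistinguishable (`ks_adjacent_groups(groups)`).
The clonotype-level classification tells the same story:

```r
qc <- classify_quality(quality_pca(pair$ir), seed = 1)
glance(qc)
#>       n var_explained_pc1 var_explained_pc2 frac_low mean_quality_low mean_quality_high
#> 1 15097             0.914            0.0851    0.656             25.9              45.2
```

65.6% of clonotypes land in the low-quality cluster — almost exactly the
generated artifact fraction (10,000 artifact singletons of 15,097
clonotypes). On the packaged cohort:

```r
cohort_range_report()
#>   platform post_filter     min      max
#> 1 RNA      FALSE            85     1273
#> 2 IR       FALSE       4050594 10274849
#> 3 RNA      TRUE             31      746
#> 4 IR       TRUE        3987468 10072564
```

Per-sample RNA-seq TCR read totals span 85–1273 (31–746 after singleton
removal); IR-seq totals span ~4.05M–10.27M (~3.99M–10.07M after).

`run_pipeline(pipeline_config(...))` chains every stage on a simulated
(or user-supplied) cohort and persists per-stage TSVs, a JSON summary and
the resolved configuration.

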