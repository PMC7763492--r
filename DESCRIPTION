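Package: repfilter
Title: Read Filtering and Cross-Platform Comparison for T-Cell Receptor
    Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of T-cell receptor (TCR) repertoire
    data obtained from targeted immune-repertoire sequencing (IR-seq) and
    bulk RNA-seq. Implements singleton-clonotype filtering with
    conservation diagnostics, support-stratified mapping-quality
    comparisons (Kolmogorov-Smirnov), PCA plus two-cluster low/high
    quality classification, shared-clonotype and retention statistics
    across platforms, relative V/D/J gene-usage profiles with Welch
    comparisons, top-N clonal-expansion summaries, and clonotype-level
    read downsampling with shared-clonotype recovery curves. Ships a
    per-sample cohort sequencing summary for 31 multiple myeloma samples
    and a synthetic paired IR-seq/RNA-seq generator with ground-truth
    labels so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
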