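#' Filter clonotypes by minimum supporting reads
#'
#' Removes every clonotype supported by fewer than `min_reads` reads. The
#' default `min_reads = 2` removes singleton clonotypes — reads supported by
#' a single observation cannot be distinguished from sequencing or mapping
#' error, and carrying them forward inflates both repertoire diversity and
#' cross-platform disagreement. Thresholds are expressed as "minimum
#' supporting reads to keep": `min_reads = 1` keeps everything,
#' `min_reads = 3` additionally drops doubletons, and so on.
#'
#' Survivor order is preserved. A removal report is attached as the
#' `"filter_report"` attribute, retrievable with [filter_report()].
#'
#' @param x A clonotype tibble.
#' @param min_reads Minimum supporting reads a clonotype needs to be kept
#'   (integer >= 1).
#' @return The filtered tibble (possibly zero rows) with a `filter_report`
#'   attribute.
#' @examples
#' tbl <- tibble::tibble(cdr3_aa = c("CASSLF", "CATFFF", "CAWGYF"),
#'                       read_count = c(5L, 1L, 1L))
#' filtered <- filter_min_reads(tbl, min_reads = 2)
#' filter_report(filtered)
#' @export
filter_min_reads <- function(x, min_reads = 2L) {
  check_clonotype_tbl(x)
  min_reads <- check_scalar_int(min_reads, 1L, "min_reads")
  keep <- x$read_count >= min_reads
  out <- x[keep, , drop = FALSE]
  n_before <- nrow(x)
  singletons <- sum(x$read_count == 1L)
  total <- sum(x$read_count)
  report <- tibble(
    min_reads = min_reads,
    clonotypes_removed = n_before - nrow(out),
    reads_removed = total - sum(out$read_count),
    singleton_clonotype_fraction =
      if (n_before > 0L) singletons / n_before else NA_real_,
    singleton_read_fraction =
      if (total > 0L) singletons / total else NA_real_
  )
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the report attached by [filter_min_reads()]
#'
#' @param x A tibble returned by [filter_min_reads()].
#' @return The one-row report tibble, or `NULL` when absent.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report", exact = TRUE)
}

#' Singleton burden of a repertoire
#'
#' The share of a repertoire taken up by singleton clonotypes, both on the
#' clonotype scale (fraction of unique clonotypes with a single supporting
#' read) and on the read scale (fraction of all reads that support a
#' singleton). Deeply sequenced IR-seq libraries typically show a large
#' clonotype-scale burden but a small read-scale one; sparse RNA-seq
#' repertoires are singleton-heavy on both scales. With several samples in
#' the input, one row per sample is returned.
#'
#' @param x A non-empty clonotype tibble.
#' @return A tibble with counts plus `singleton_clonotype_fraction` and
#'   `singleton_read_fraction`.
#' @examples
#' tbl <- tibble::tibble(cdr3_aa = c("CASSLF", "CATFFF", "CAWGYF"),
#'                       read_count = c(5L, 1L, 1L))
#' singleton_stats(tbl)
#' @export
singleton_stats <- function(x) {
  check_clonotype_tbl(x)
  if (nrow(x) == 0L) {
    abort("Singleton fractions are undefined for an empty sample.",
          class = "repfilter_argument_error")
  }
  summarize_repertoire(x) |>
    mutate(
      singleton_clonotype_fraction =
        .data$singleton_clonotypes / .data$unique_clonotypes,
      singleton_read_fraction =
        .data$singleton_clonotypes / .data$total_reads
    )
}
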