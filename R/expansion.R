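# Clonal-expansion summaries: cumulative frequency of the top-N clonotypes.

#' Cumulative frequency of the top-N clonotypes
#'
#' Ranks the clonotypes of each sample by supporting-read count (ties broken
#' lexicographically on the CDR3 key, for determinism) and returns the
#' summed relative frequency of the `n` most frequent ones. Values near 1
#' indicate a repertoire concentrated in few clones (clonal expansion).
#'
#' @param x A non-empty clonotype tibble, possibly stacking samples.
#' @param n Number of top clonotypes to sum (integer >= 1). When `n` is at
#'   least the number of clonotypes the proportion is exactly 1.
#' @return A tibble `sample_id` (when present), `n`, `proportion`.
#' @examples
#' tbl <- tibble::tibble(cdr3_aa = c("CA", "CB", "CC", "CD"),
#'                       read_count = c(5L, 3L, 1L, 1L))
#' top_n_proportion(tbl, 2)   # (5 + 3) / 10
#' @export
top_n_proportion <- function(x, n = 10L) {
  check_clonotype_tbl(x)
  n <- check_scalar_int(n, 1L, "n")
  if (nrow(x) == 0L) {
    abort("Top-N proportion is undefined for an empty sample.",
          class = "repfilter_argument_error")
  }
  if (!"sample_id" %in% names(x)) {
    x <- mutate(x, sample_id = "sample")
  }
  x |>
    group_by(.data$sample_id) |>
    arrange(desc(.data$read_count), .data$cdr3_aa, .by_group = TRUE) |>
    summarise(
      n = n,
      proportion = sum(head(.data$read_count, n)) / sum(.data$read_count),
      .groups = "drop"
    )
}

#' Compare clonal-expansion proportions between two conditions
#'
#' Welch two-sample t-test of per-sample top-N proportions between two
#' conditions (typically before vs after singleton filtering), plus the
#' mean shift. Proportions after filtering are computed on the post-filter
#' read total, so a shrinking denominator alone can raise them.
#'
#' @param before,after Numeric vectors of per-sample proportions, or
#'   tibbles from [top_n_proportion()] (the `proportion` column is used).
#'   At least two samples per condition.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `mean_shift`
#'   (`mean(after) - mean(before)`), `degenerate`.
#' @export
compare_expansion <- function(before, after) {
  get_prop <- function(v) {
    if (is.data.frame(v)) v$proportion else as.numeric(v)
  }
  a <- get_prop(before)
  b <- get_prop(after)
  if (length(a) < 2L || length(b) < 2L) {
    abort("Need at least two samples per condition.",
          class = "repfilter_argument_error")
  }
  welch_compare(b, a) |>
    mutate(mean_shift = mean(b) - mean(a))
}

#' Guard against under-sized samples in top-N comparisons
#'
#' Sparse repertoires can retain fewer clonotypes than the requested top-N
#' after filtering; their top-N proportion is trivially 1 and would distort
#' a comparison. The guard is `TRUE` when the sample has fewer than `n`
#' unique clonotypes and should be excluded (with a warning upstream).
#'
#' @param x A clonotype tibble (one sample).
#' @param n The top-N of the intended comparison.
#' @return `TRUE` when the sample has fewer than `n` clonotypes.
#' @export
min_clonotype_guard <- function(x, n) {
  check_clonotype_tbl(x)
  n <- check_scalar_int(n, 1L, "n")
  nrow(x) < n
}
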