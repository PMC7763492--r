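# Shared-clonotype analysis: overlap within a cohort, between paired
# platforms, retention of the overlap under read filtering, and frequency
# correlation of shared clonotypes.

#' Clonotypes shared across samples
#'
#' Finds clonotype keys present in at least `min_samples` of the samples in
#' a stacked clonotype tibble, with each key's sample-support count.
#'
#' @param x A clonotype tibble with a `sample_id` column covering two or
#'   more samples. A warning is raised if several platforms are mixed.
#' @param min_samples Minimum number of samples a key must appear in
#'   (integer >= 2).
#' @param key Clonotype identity: `"aa"` (CDR3 amino-acid sequence, the
#'   default) or `"vj_aa"` (V/J-qualified).
#' @return A tibble `clonotype_key`, `n_samples`, sorted by decreasing
#'   support.
#' @export
shared_across_samples <- function(x, min_samples = 2L, key = c("aa", "vj_aa")) {
  check_clonotype_tbl(x)
  min_samples <- check_scalar_int(min_samples, 2L, "min_samples")
  if (!"sample_id" %in% names(x) || n_distinct(x$sample_id) < 2L) {
    abort("`x` must stack at least two samples (column `sample_id`).",
          class = "repfilter_argument_error")
  }
  if ("platform" %in% names(x) && n_distinct(x$platform) > 1L) {
    warn("`x` mixes platforms; sample-support counts pool across them.")
  }
  tibble(sample_id = x$sample_id, clonotype_key = clonotype_key(x, key)) |>
    distinct() |>
    count(.data$clonotype_key, name = "n_samples") |>
    filter(.data$n_samples >= min_samples) |>
    arrange(desc(.data$n_samples), .data$clonotype_key)
}

#' Clonotypes shared between paired platforms
#'
#' Intersection of the clonotype keys of a matched IR-seq/RNA-seq pair,
#' with each platform's supporting read count for the shared key.
#'
#' @param ir,rna Clonotype tibbles of the two platforms for one sample.
#'   A warning is raised when their `sample_id`s disagree.
#' @inheritParams shared_across_samples
#' @return A tibble `clonotype_key`, `ir_reads`, `rna_reads` (zero rows for
#'   a disjoint pair).
#' @export
paired_shared <- function(ir, rna, key = c("aa", "vj_aa")) {
  check_clonotype_tbl(ir)
  check_clonotype_tbl(rna)
  if (all(c("sample_id") %in% names(ir)) && all(c("sample_id") %in% names(rna)) &&
      nrow(ir) && nrow(rna) &&
      !identical(unique(ir$sample_id), unique(rna$sample_id))) {
    warn("`ir` and `rna` carry different sample_ids; treating as a pair anyway.")
  }
  a <- tibble(clonotype_key = clonotype_key(ir, key), ir_reads = ir$read_count)
  b <- tibble(clonotype_key = clonotype_key(rna, key), rna_reads = rna$read_count)
  dplyr::inner_join(a, b, by = "clonotype_key") |>
    arrange(.data$clonotype_key)
}

#' Retention of shared clonotypes under read filtering
#'
#' Counts the clonotypes shared between a matched pair before and after
#' applying the same minimum-read filter to both sides, and the fraction of
#' the original overlap eliminated by the filter. Because singletons
#' dominate sparse repertoires, even the mild `min_reads = 2` filter can
#' eliminate most of the raw overlap — the retained overlap is the
#' reliable part.
#'
#' @inheritParams paired_shared
#' @param min_reads Threshold handed to [filter_min_reads()] on both sides.
#' @return A one-row tibble: `min_reads`, `shared_before`, `shared_after`,
#'   `eliminated_fraction` (`NA` when there is no overlap to begin with).
#' @export
retention_under_filter <- function(ir, rna, min_reads = 2L,
                                   key = c("aa", "vj_aa")) {
  min_reads <- check_scalar_int(min_reads, 1L, "min_reads")
  before <- nrow(paired_shared(ir, rna, key))
  after <- nrow(paired_shared(filter_min_reads(ir, min_reads),
                              filter_min_reads(rna, min_reads), key))
  tibble(
    min_reads = min_reads,
    shared_before = before,
    shared_after = after,
    eliminated_fraction = if (before > 0L) 1 - after / before else NA_real_
  )
}

#' Frequency correlation of shared clonotypes
#'
#' For each matched pair, both sides are filtered at `min_reads`, relative
#' clonotype frequencies are recomputed on the post-filter read totals, and
#' the (frequency, frequency) points of all shared clonotypes are pooled
#' across pairs. The correlation of the pooled cloud measures how well the
#' sparse platform tracks the deep one; per-pair correlations are kept for
#' transparency.
#'
#' @param pairs A list of pairs, each a list with elements `ir` and `rna`
#'   (clonotype tibbles of one matched sample).
#' @param min_reads Threshold applied to both sides of every pair before
#'   frequencies are computed; `1` leaves the data unfiltered.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @inheritParams paired_shared
#' @return An object of class `shared_freq_cor`: pooled `estimate`, the
#'   pooled `points` and a `per_pair` table. See [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
shared_frequency_correlation <- function(pairs, min_reads = 2L,
                                         method = c("pearson", "spearman"),
                                         key = c("aa", "vj_aa")) {
  method <- match.arg(method)
  min_reads <- check_scalar_int(min_reads, 1L, "min_reads")
  if (!length(pairs)) {
    abort("`pairs` must hold at least one (ir, rna) pair.",
          class = "repfilter_argument_error")
  }
  points <- purrr::imap(pairs, function(p, i) {
    ir <- filter_min_reads(p$ir, min_reads)
    rna <- filter_min_reads(p$rna, min_reads)
    shared <- paired_shared(ir, rna, key)
    if (nrow(shared) == 0L) {
      return(NULL)
    }
    sid <- if ("sample_id" %in% names(p$ir) && nrow(p$ir)) {
      unique(p$ir$sample_id)[1L]
    } else {
      as.character(i)
    }
    tibble(sample_id = sid,
           clonotype_key = shared$clonotype_key,
           freq_ir = shared$ir_reads / sum(ir$read_count),
           freq_rna = shared$rna_reads / sum(rna$read_count))
  }) |> bind_rows()
  if (nrow(points) < 2L) {
    abort("Fewer than two shared clonotype observations after filtering.",
          class = "repfilter_degenerate_error")
  }
  if (stats::sd(points$freq_ir) == 0 || stats::sd(points$freq_rna) == 0) {
    abort("Zero variance in shared clonotype frequencies; correlation undefined.",
          class = "repfilter_degenerate_error")
  }
  per_pair <- points |>
    group_by(.data$sample_id) |>
    summarise(
      n_shared = dplyr::n(),
      estimate = if (dplyr::n() >= 2L &&
                     stats::sd(.data$freq_ir) > 0 &&
                     stats::sd(.data$freq_rna) > 0) {
        cor(.data$freq_ir, .data$freq_rna, method = method)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  structure(
    list(estimate = cor(points$freq_ir, points$freq_rna, method = method),
         method = method, min_reads = min_reads,
         n_points = nrow(points), points = points, per_pair = per_pair),
    class = "shared_freq_cor"
  )
}

#' @export
print.shared_freq_cor <- function(x, ...) {
  cat(sprintf(
    "Shared-clonotype frequency correlation (%s, min_reads = %d)\n",
    x$method, x$min_reads))
  cat(sprintf("  pooled r = %.4f over %d shared clonotype observations (%d pairs)\n",
              x$estimate, x$n_points, nrow(x$per_pair)))
  invisible(x)
}

#' @rdname shared_frequency_correlation
#' @param x A `shared_freq_cor` object.
#' @param ... Unused.
#' @export
tidy.shared_freq_cor <- function(x, ...) {
  x$per_pair
}

#' @rdname shared_frequency_correlation
#' @export
glance.shared_freq_cor <- function(x, ...) {
  tibble(estimate = x$estimate, method = x$method, min_reads = x$min_reads,
         n_points = x$n_points, n_pairs = nrow(x$per_pair))
}

#' @rdname shared_frequency_correlation
#' @param object A `shared_freq_cor` object.
#' @export
autoplot.shared_freq_cor <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$freq_ir, y = .data$freq_rna)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "IR-seq clonotype frequency",
      y = "RNA-seq clonotype frequency",
      title = sprintf("Shared clonotype frequencies (r = %.3f, min reads = %d)",
                      object$estimate, object$min_reads)
    )
}
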