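# Cohort-level sequencing summaries.
#
# The package ships a per-sample sequencing summary for a cohort of 31
# multiple myeloma bone-marrow samples profiled with both bulk RNA-seq and
# targeted immune-repertoire sequencing (IR-seq): per sample, the
# genome-mapped read total of the RNA library plus, for each platform, the
# TCR-region read total, the number of unique CDR3 amino-acid clonotypes and
# the number of singleton clonotypes.

cohort_summary_cols <- c("sample_id", "star_mapped_reads",
                         "rna_total_reads", "rna_unique_clonotypes",
                         "rna_singletons", "ir_total_reads",
                         "ir_unique_clonotypes", "ir_singletons")

#' Path to the packaged multiple-myeloma cohort summary
#'
#' @return Path of the TSV shipped in `inst/extdata`.
#' @export
cohort_summary_path <- function() {
  system.file("extdata", "mm_cohort_summary.tsv", package = "repfilter",
              mustWork = TRUE)
}

#' Read a cohort sequencing summary
#'
#' Reads a per-sample cohort summary table and validates, for every row and
#' both platforms, the counting identity
#' `singletons <= unique clonotypes <= total reads`.
#'
#' @param path TSV with the eight columns named in the packaged fixture;
#'   defaults to the packaged multiple-myeloma cohort.
#' @return A tibble with one row per sample.
#' @examples
#' mm <- read_cohort_summary()
#' nrow(mm)
#' @export
read_cohort_summary <- function(path = cohort_summary_path()) {
  if (!file.exists(path)) {
    abort(sprintf("Cohort summary `%s` does not exist.", path),
          class = "repfilter_io_error")
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(cohort_summary_cols, names(x))
  if (length(missing)) {
    abort(sprintf("Cohort summary lacks column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "repfilter_format_error")
  }
  x <- x[, cohort_summary_cols]
  num <- cohort_summary_cols[-1]
  bad_na <- !stats::complete.cases(x[num])
  ok <- !bad_na &
    x$rna_singletons <= x$rna_unique_clonotypes &
    x$rna_unique_clonotypes <= x$rna_total_reads &
    x$ir_singletons <= x$ir_unique_clonotypes &
    x$ir_unique_clonotypes <= x$ir_total_reads
  if (any(!ok)) {
    abort(sprintf(
      "Cohort summary row(s) violate singletons <= unique <= total: %s.",
      paste(head(x$sample_id[!ok], 5L), collapse = ", ")),
      class = "repfilter_parse_error")
  }
  x
}

#' Cohort-wide read-count ranges
#'
#' Minimum and maximum per-sample TCR-region read totals across a cohort,
#' either as sequenced (`post_filter = FALSE`) or after singleton-clonotype
#' removal (`post_filter = TRUE`). Because every singleton clonotype carries
#' exactly one read, the post-filter per-sample read total under a
#' minimum-support threshold of 2 equals `total reads - singletons` exactly.
#'
#' @param rows A cohort summary tibble from [read_cohort_summary()].
#' @param platform `"RNA"` or `"IR"`.
#' @param post_filter Use post-singleton-removal read totals?
#' @return A one-row tibble: `platform`, `post_filter`, `min`, `max`.
#' @examples
#' cohort_read_ranges(read_cohort_summary(), "RNA")
#' @export
cohort_read_ranges <- function(rows, platform = c("RNA", "IR"),
                               post_filter = FALSE) {
  platform <- match.arg(platform)
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    abort("`rows` must be a non-empty cohort summary.",
          class = "repfilter_argument_error")
  }
  totals <- if (platform == "RNA") rows$rna_total_reads else rows$ir_total_reads
  if (post_filter) {
    sing <- if (platform == "RNA") rows$rna_singletons else rows$ir_singletons
    totals <- totals - sing
  }
  tibble(platform = platform, post_filter = post_filter,
         min = min(totals), max = max(totals))
}

#' Cohort range report
#'
#' Pre- and post-filter read-count ranges for both platforms of a cohort
#' summary, in one table.
#'
#' @param path Cohort summary TSV; defaults to the packaged cohort.
#' @return A four-row tibble (`platform` x `post_filter`).
#' @examples
#' cohort_range_report()
#' @export
cohort_range_report <- function(path = cohort_summary_path()) {
  rows <- read_cohort_summary(path)
  grid <- expand.grid(platform = c("RNA", "IR"), post_filter = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  purrr::pmap(grid, function(platform, post_filter) {
    cohort_read_ranges(rows, platform, post_filter)
  }) |> bind_rows()
}
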