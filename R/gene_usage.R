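# Relative V/D/J gene usage and between-platform comparison.

usage_gene_col <- c(V = "v_gene", D = "d_gene", J = "j_gene")

#' Relative gene usage of a repertoire
#'
#' For one gene category (V, D or J) and each sample, counts the clonotypes
#' calling each gene and scales by the category's largest clonotype count in
#' that sample, so the most used gene has usage exactly 1 and every other
#' gene a value in (0, 1]. Clonotypes are counted once regardless of read
#' count; records without a call in the category are excluded.
#'
#' @param x A clonotype tibble, possibly stacking several samples.
#' @param category `"V"`, `"D"` or `"J"`.
#' @return A tibble `sample_id` (when present), `category`, `gene`,
#'   `n_clonotypes`, `usage`. Zero rows, with a warning, when the input has
#'   no call in the category.
#' @export
relative_usage <- function(x, category = c("V", "D", "J")) {
  check_clonotype_tbl(x)
  category <- match.arg(category)
  col <- usage_gene_col[[category]]
  empty <- tibble(sample_id = character(), category = character(),
                  gene = character(), n_clonotypes = integer(),
                  usage = double())
  if (!col %in% names(x)) {
    warn(sprintf("No `%s` column; returning empty usage table.", col))
    return(empty)
  }
  called <- x[!is.na(x[[col]]) & nzchar(x[[col]]), , drop = FALSE]
  if (nrow(called) == 0L) {
    warn(sprintf("No %s-gene calls; returning empty usage table.", category))
    return(empty)
  }
  if (!"sample_id" %in% names(called)) {
    called$sample_id <- "sample"
  }
  called |>
    count(.data$sample_id, gene = .data[[col]], name = "n_clonotypes") |>
    group_by(.data$sample_id) |>
    mutate(category = category,
           usage = .data$n_clonotypes / max(.data$n_clonotypes)) |>
    ungroup() |>
    select("sample_id", "category", "gene", "n_clonotypes", "usage")
}

#' Compare gene usage between platforms
#'
#' Per-gene Welch two-sample t-test (unequal variances) of the sample-wise
#' relative usage values between IR-seq and RNA-seq. The gene set is the
#' union over both platforms, and a gene absent from a sample contributes
#' usage 0 for that sample — absence is informative in the sparse platform.
#' Genes whose within-group variances are both zero are flagged
#' `degenerate` (p = 1 on equal means, p = 0 otherwise).
#'
#' @param ir_usage,rna_usage Usage tables from [relative_usage()], each
#'   covering at least two samples of one platform (same category).
#' @param alpha Significance level.
#' @param adjust `"none"` (default: raw Welch p-values are thresholded) or
#'   `"BH"`.
#' @return A tibble with one row per gene: per-platform means, Welch
#'   `t_statistic`, `df`, `p_value` (and `p_adjusted` under `"BH"`),
#'   `significant`, `degenerate`.
#' @export
compare_usage <- function(ir_usage, rna_usage, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  for (u in list(ir_usage, rna_usage)) {
    if (!is.data.frame(u) || !all(c("sample_id", "gene", "usage") %in% names(u))) {
      abort("Usage tables must have columns sample_id, gene, usage.",
            class = "repfilter_argument_error")
    }
  }
  if (n_distinct(ir_usage$sample_id) < 2L || n_distinct(rna_usage$sample_id) < 2L) {
    abort("Need at least two samples per platform.",
          class = "repfilter_argument_error")
  }
  genes <- sort(union(ir_usage$gene, rna_usage$gene))
  fill_grid <- function(u) {
    tidyr::expand_grid(sample_id = unique(u$sample_id), gene = genes) |>
      left_join(u[, c("sample_id", "gene", "usage")],
                by = c("sample_id", "gene")) |>
      mutate(usage = tidyr::replace_na(.data$usage, 0))
  }
  gi <- fill_grid(ir_usage)
  gr <- fill_grid(rna_usage)
  res <- purrr::map(genes, function(g) {
    a <- gi$usage[gi$gene == g]
    b <- gr$usage[gr$gene == g]
    w <- welch_compare(a, b)
    tibble(gene = g, n_ir = length(a), n_rna = length(b),
           mean_ir = mean(a), mean_rna = mean(b)) |>
      dplyr::bind_cols(w)
  }) |> bind_rows()
  if (adjust == "BH") {
    res <- res |> mutate(p_adjusted = p.adjust(.data$p_value, "BH"),
                         significant = .data$p_adjusted < alpha)
  } else {
    res <- res |> mutate(significant = .data$p_value < alpha)
  }
  if (any(res$degenerate)) {
    warn(sprintf("%d gene(s) had zero variance on both platforms (flagged).",
                 sum(res$degenerate)))
  }
  res
}

#' Plot per-sample relative gene usage
#'
#' Box plots of sample-wise relative usage per gene, split by platform when
#' usage tables from both platforms are supplied.
#'
#' @param ... One or more usage tables from [relative_usage()]; give them
#'   names (e.g. `IR = ..., RNA = ...`) to label the platforms.
#' @param top Restrict to the `top` genes by mean usage (default all).
#' @return A ggplot object.
#' @export
plot_usage <- function(..., top = NULL) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(!nzchar(names(tabs)))) {
    names(tabs) <- paste0("set", seq_along(tabs))
  }
  u <- purrr::imap(tabs, ~ mutate(.x, platform = .y)) |> bind_rows()
  ord <- u |>
    group_by(.data$gene) |>
    summarise(m = mean(.data$usage), .groups = "drop") |>
    arrange(desc(.data$m))
  if (!is.null(top)) {
    ord <- head(ord, top)
    u <- filter(u, .data$gene %in% ord$gene)
  }
  u$gene <- factor(u$gene, levels = ord$gene)
  ggplot2::ggplot(u, ggplot2::aes(x = .data$gene, y = .data$usage,
                                  fill = .data$platform)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "relative usage (max gene = 1)",
                  fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
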