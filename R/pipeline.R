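# End-to-end orchestration: simulate (or ingest) a cohort of matched
# pairs and chain every analysis stage, persisting auditable outputs.

#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] in one validated
#' list. Every run records the resolved configuration next to its outputs,
#' because filtering conclusions depend on how the pipeline is set.
#'
#' @param n_pairs Number of matched pairs to simulate (ignored when
#'   `pairs` are handed to [run_pipeline()] directly).
#' @param sim A [sim_config()] for the synthetic cohort.
#' @param min_reads Minimum-support threshold used by the filtering,
#'   retention, usage, expansion and downsampling stages.
#' @param alpha Significance level shared by all tests.
#' @param adjust Multiple-testing adjustment for the KS family.
#' @param cap Support-group pooling cap (see [group_by_support()]).
#' @param top_n Top-N sizes for the clonal-expansion stage.
#' @param proportions Depth grid of the downsampling stage.
#' @param n_downsample_seeds Number of replicate downsampling runs.
#' @param seed Master seed; overrides `sim$seed`.
#' @param out_dir Directory for persisted outputs, or `NULL` to keep
#'   results in memory only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_pairs = 5L, sim = sim_config(),
                            min_reads = 2L, alpha = 0.05,
                            adjust = c("BH", "bonferroni"), cap = 10L,
                            top_n = c(10L, 5L),
                            proportions = c(0.01, 0.05, 0.1, 0.2, 0.3,
                                            0.4, 0.5, 0.6),
                            n_downsample_seeds = 3L, seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  seed <- check_scalar_int(seed, -.Machine$integer.max, "seed")
  sim$seed <- seed
  structure(list(
    n_pairs = check_scalar_int(n_pairs, 1L, "n_pairs"),
    sim = sim,
    min_reads = check_scalar_int(min_reads, 1L, "min_reads"),
    alpha = alpha,
    adjust = match.arg(adjust),
    cap = check_scalar_int(cap, 2L, "cap"),
    top_n = vapply(top_n, check_scalar_int, 1L, min = 1L, arg = "top_n"),
    proportions = proportions,
    n_downsample_seeds = check_scalar_int(n_downsample_seeds, 1L,
                                          "n_downsample_seeds"),
    seed = seed,
    out_dir = out_dir
  ), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s", name,
                  conditionMessage(e)),
          class = "repfilter_stage_error", parent = e)
  })
}

#' Run the full repertoire-filtering pipeline
#'
#' Chains every stage on a cohort of matched IR-seq/RNA-seq pairs:
#' per-sample summaries and singleton burden; minimum-read filtering with
#' conservation reports; shared-clonotype retention and frequency
#' correlation before/after filtering; support-stratified KS quality
#' comparisons plus PCA/2-means quality classification on the first pair's
#' IR sample; relative V/J gene usage comparison on the filtered samples;
#' top-N clonal expansion before/after filtering; and downsampling
#' recovery curves of the first pair (against its filtered RNA sample)
#' over replicate seeds. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param pairs Optionally, a pre-built list of pairs (each a list with
#'   `sample_id`, `ir`, `rna`); defaults to simulating
#'   `config$n_pairs` pairs from `config$sim`.
#' @return A list of class `pipeline_result` with one element per stage
#'   plus the resolved configuration. When `config$out_dir` is set, every
#'   tabular result is written as TSV, a JSON summary as
#'   `summary.json` and the resolved configuration as `config.yaml`.
#' @export
run_pipeline <- function(config = pipeline_config(), pairs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(pairs)) {
    pairs <- run_stage("simulate", simulate_cohort(config$sim, config$n_pairs))
  }

  samples <- purrr::map(pairs, ~ bind_rows(.x$ir, .x$rna)) |> bind_rows()
  summaries <- run_stage("summarize", summarize_repertoire(samples))
  singletons <- run_stage("singleton_stats", singleton_stats(samples))

  filt <- run_stage("filter", purrr::map(pairs, function(p) {
    list(ir = filter_min_reads(p$ir, config$min_reads),
         rna = filter_min_reads(p$rna, config$min_reads))
  }))
  filter_reports <- purrr::map2(pairs, filt, function(p, f) {
    bind_rows(
      mutate(filter_report(f$ir), sample_id = p$sample_id, platform = "IR"),
      mutate(filter_report(f$rna), sample_id = p$sample_id, platform = "RNA")
    )
  }) |> bind_rows()

  retention <- run_stage("retention", purrr::map(pairs, function(p) {
    mutate(retention_under_filter(p$ir, p$rna, config$min_reads),
           sample_id = p$sample_id)
  }) |> bind_rows())
  correlation <- run_stage("correlation", list(
    before = shared_frequency_correlation(pairs, min_reads = 1L),
    after = shared_frequency_correlation(pairs, min_reads = config$min_reads)
  ))

  quality <- run_stage("quality", {
    ir1 <- pairs[[1L]]$ir
    groups <- group_by_support(ir1, cap = config$cap)
    qc <- classify_quality(quality_pca(ir1), seed = config$seed)
    list(
      groups = groups,
      ks_singleton = ks_singleton_vs_groups(groups, config$alpha,
                                            config$adjust),
      ks_adjacent = ks_adjacent_groups(groups, config$alpha, config$adjust),
      classification = qc,
      composition = low_quality_composition(qc, groups)
    )
  })

  usage <- run_stage("usage", {
    ir_f <- purrr::map(filt, "ir") |> bind_rows()
    rna_f <- purrr::map(filt, "rna") |> bind_rows()
    purrr::map(c(V = "V", J = "J"), function(cat) {
      iu <- relative_usage(ir_f, cat)
      ru <- relative_usage(rna_f, cat)
      list(ir = iu, rna = ru,
           comparison = compare_usage(iu, ru, alpha = config$alpha))
    })
  })

  expansion <- run_stage("expansion", purrr::map(config$top_n, function(nt) {
    per_platform <- purrr::map(c(IR = "ir", RNA = "rna"), function(pf) {
      pre <- purrr::map(pairs, pf)
      post <- purrr::map(filt, pf)
      keep <- purrr::map_lgl(post, ~ nrow(.x) > 0 && !min_clonotype_guard(.x, nt))
      if (sum(keep) < 2L) {
        return(NULL)
      }
      before <- purrr::map(pairs[keep], ~ top_n_proportion(.x[[pf]], nt)) |>
        bind_rows()
      after <- purrr::map(filt[keep], ~ top_n_proportion(.x[[pf]], nt)) |>
        bind_rows()
      list(before = before, after = after,
           comparison = mutate(compare_expansion(before, after),
                               n = nt, n_samples = sum(keep)))
    })
    per_platform
  }) |> setNames(paste0("top", config$top_n)))

  downsampling <- run_stage("downsample", {
    ir1 <- pairs[[1L]]$ir
    rna1 <- filter_min_reads(pairs[[1L]]$rna, config$min_reads)
    curves <- purrr::map(seq_len(config$n_downsample_seeds), function(s) {
      mutate(recovery_curve(ir1, rna1, config$proportions,
                            seed = config$seed + s),
             seed = config$seed + s)
    }) |> bind_rows()
    sig <- if (config$n_downsample_seeds >= 2L) {
      recovery_significance(curves, config$alpha)
    } else {
      NULL
    }
    list(curves = curves, significance = sig)
  })

  result <- structure(list(
    config = config,
    summaries = summaries,
    singleton_stats = singletons,
    filter_reports = filter_reports,
    retention = retention,
    correlation = correlation,
    quality = quality,
    usage = usage,
    expansion = expansion,
    downsampling = downsampling
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir)
  }
  result
}

pipeline_summary_list <- function(x) {
  exp_comp <- purrr::imap(x$expansion, function(e, nm) {
    purrr::compact(purrr::map(e, "comparison"))
  })
  list(
    seed = x$config$seed,
    min_reads = x$config$min_reads,
    singleton_stats = x$singleton_stats,
    retention = x$retention,
    correlation = list(before = glance(x$correlation$before),
                       after = glance(x$correlation$after)),
    ks_singleton = x$quality$ks_singleton,
    ks_adjacent = x$quality$ks_adjacent,
    low_quality_composition = x$quality$composition,
    usage_significant = purrr::map(x$usage,
                                   ~ sum(.x$comparison$significant)),
    expansion = exp_comp,
    recovery_significance = x$downsampling$significance
  )
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(obj, name) {
    readr::write_tsv(obj, file.path(out_dir, paste0(name, ".tsv")),
                     progress = FALSE)
  }
  tsv(result$summaries, "summaries")
  tsv(result$singleton_stats, "singleton_stats")
  tsv(result$filter_reports, "filter_reports")
  tsv(result$retention, "retention")
  tsv(result$quality$ks_singleton, "ks_singleton")
  tsv(result$quality$ks_adjacent, "ks_adjacent")
  tsv(result$quality$composition, "low_quality_composition")
  tsv(tidy(result$quality$classification), "quality_labels")
  for (cat in names(result$usage)) {
    tsv(result$usage[[cat]]$comparison, paste0("usage_", cat))
  }
  tsv(result$downsampling$curves, "recovery_curves")
  if (!is.null(result$downsampling$significance)) {
    tsv(result$downsampling$significance, "recovery_significance")
  }
  jsonlite::write_json(pipeline_summary_list(result),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  cfg <- result$config
  cfg_list <- unclass(cfg)
  cfg_list$sim <- unclass(cfg_list$sim)
  cfg_list$sim$v_gene_table <- as.list(cfg_list$sim$v_gene_table)
  cfg_list$sim$d_gene_table <- as.list(cfg_list$sim$d_gene_table)
  cfg_list$sim$j_gene_table <- as.list(cfg_list$sim$j_gene_table)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("repfilter pipeline result\n")
  cat(sprintf("  %d sample pair(s), min_reads = %d, seed = %d\n",
              nrow(x$retention), x$config$min_reads, x$config$seed))
  cat(sprintf("  pooled shared-frequency r: %.3f (raw) -> %.3f (filtered)\n",
              x$correlation$before$estimate, x$correlation$after$estimate))
  el <- x$retention$eliminated_fraction
  cat(sprintf("  mean shared-clonotype elimination at threshold: %.1f%%\n",
              100 * mean(el, na.rm = TRUE)))
  invisible(x)
}
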