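# Clonotype-level read downsampling and shared-clonotype recovery curves.
#
# Downsampling draws floor(proportion * total_reads) reads without
# replacement from the pool of reads labelled by clonotype (multivariate
# hypergeometric), which is equivalent in distribution to subsampling the
# underlying read file and re-tabulating, under the assumption that each
# read supports exactly one clonotype.

#' Randomly thin a repertoire to a fraction of its reads
#'
#' Draws `floor(proportion * total_reads)` reads without replacement from
#' the sample's read pool and re-tabulates clonotype counts; clonotypes
#' drawn zero times are dropped. Quality features and gene calls of the
#' surviving clonotypes are carried over unchanged.
#'
#' @param x A clonotype tibble.
#' @param proportion Fraction of reads to keep, in (0, 1]. `1` returns the
#'   sample unchanged.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return The thinned clonotype tibble. A target of zero reads yields an
#'   empty sample with a warning.
#' @export
downsample_counts <- function(x, proportion, seed = 1L) {
  check_clonotype_tbl(x)
  seed <- check_scalar_int(seed, -.Machine$integer.max, "seed")
  if (!is.numeric(proportion) || length(proportion) != 1L ||
      is.na(proportion) || proportion <= 0 || proportion > 1) {
    abort("`proportion` must be a single value in (0, 1].",
          class = "repfilter_argument_error")
  }
  if (proportion == 1) {
    return(x)
  }
  total <- sum(x$read_count)
  target <- floor(proportion * total)
  if (target == 0L) {
    warn("Downsampling target is 0 reads; returning an empty sample.")
    return(x[0L, , drop = FALSE])
  }
  idx <- withr::with_seed(seed, sample.int(total, target))
  cum <- cumsum(as.numeric(x$read_count))
  clone <- findInterval(idx - 1L, cum) + 1L
  counts <- tabulate(clone, nbins = nrow(x))
  out <- x[counts > 0L, , drop = FALSE]
  out$read_count <- as.integer(counts[counts > 0L])
  out
}

#' Shared-clonotype recovery across a depth grid
#'
#' Thins a deep IR-seq sample to each proportion of the grid and records,
#' per depth, the number of unique clonotypes and the number shared with a
#' paired RNA-seq sample. With `nested = TRUE` (default) the read subsets
#' are nested across proportions — one random read permutation is prefixed
#' at each target — so both counts are non-decreasing in depth exactly, not
#' just in expectation. Pass the RNA sample already filtered (e.g. through
#' [filter_min_reads()]) to measure recovery of its reliable clonotypes.
#'
#' @param ir Deep clonotype tibble to thin (non-empty).
#' @param rna Paired clonotype tibble providing the reference key set; may
#'   be empty, in which case all shared counts are zero.
#' @param proportions Strictly increasing depth fractions in (0, 1].
#' @param seed Integer seed for the read permutation / draws.
#' @param nested Nest subsets across proportions (exact monotonicity)?
#'   `FALSE` draws each depth independently.
#' @inheritParams shared_across_samples
#' @return A tibble `proportion`, `total_reads`, `unique_clonotypes`,
#'   `shared_with_rna`.
#' @export
recovery_curve <- function(ir, rna,
                           proportions = c(0.01, 0.05, 0.1, 0.2, 0.3,
                                           0.4, 0.5, 0.6),
                           seed = 1L, nested = TRUE, key = c("aa", "vj_aa")) {
  check_clonotype_tbl(ir)
  check_clonotype_tbl(rna)
  seed <- check_scalar_int(seed, -.Machine$integer.max, "seed")
  if (nrow(ir) == 0L) {
    abort("`ir` must be non-empty.", class = "repfilter_argument_error")
  }
  if (!is.numeric(proportions) || !length(proportions) ||
      any(is.na(proportions)) || any(proportions <= 0 | proportions > 1) ||
      is.unsorted(proportions, strictly = TRUE)) {
    abort("`proportions` must be strictly increasing values in (0, 1].",
          class = "repfilter_argument_error")
  }
  ir_keys <- clonotype_key(ir, key)
  rna_keys <- unique(clonotype_key(rna, key))
  total <- sum(ir$read_count)
  targets <- floor(proportions * total)

  counts_at <- if (nested) {
    clone_of_read <- rep.int(seq_len(nrow(ir)), ir$read_count)
    perm <- withr::with_seed(seed, sample.int(total))
    function(i) tabulate(clone_of_read[perm[seq_len(targets[i])]],
                         nbins = nrow(ir))
  } else {
    function(i) {
      sub <- downsample_counts(ir, proportions[i], seed = seed + i)
      counts <- integer(nrow(ir))
      counts[match(clonotype_key(sub, key), ir_keys)] <- sub$read_count
      counts
    }
  }

  purrr::map(seq_along(proportions), function(i) {
    counts <- counts_at(i)
    seen <- counts > 0L
    tibble(proportion = proportions[i],
           total_reads = sum(counts),
           unique_clonotypes = sum(seen),
           shared_with_rna = length(intersect(ir_keys[seen], rna_keys)))
  }) |> bind_rows()
}

#' Depth effect on shared-clonotype recovery
#'
#' Welch comparison of `shared_with_rna` between adjacent depth levels
#' across replicate downsampling runs. A flat recovery curve (no
#' significant adjacent difference) means the shallower depth already
#' recovers the reliably shared clonotypes.
#'
#' @param curves Recovery curves of several replicates stacked in one
#'   tibble with columns `seed`, `proportion`, `shared_with_rna` (at least
#'   two replicates).
#' @param alpha Significance level.
#' @return A tibble with one row per adjacent proportion pair:
#'   `proportion_a`, `proportion_b`, Welch `t_statistic`, `df`, `p_value`,
#'   `significant`, `degenerate`.
#' @export
recovery_significance <- function(curves, alpha = 0.05) {
  need <- c("seed", "proportion", "shared_with_rna")
  if (!is.data.frame(curves) || !all(need %in% names(curves))) {
    abort("`curves` must have columns seed, proportion, shared_with_rna.",
          class = "repfilter_argument_error")
  }
  if (n_distinct(curves$seed) < 2L) {
    abort("Need recovery curves from at least two seeds.",
          class = "repfilter_argument_error")
  }
  props <- sort(unique(curves$proportion))
  purrr::map(seq_len(length(props) - 1L), function(i) {
    a <- curves$shared_with_rna[curves$proportion == props[i]]
    b <- curves$shared_with_rna[curves$proportion == props[i + 1L]]
    welch_compare(a, b) |>
      mutate(proportion_a = props[i], proportion_b = props[i + 1L],
             significant = !.data$degenerate & .data$p_value < alpha) |>
      select("proportion_a", "proportion_b", "t_statistic", "df",
             "p_value", "significant", "degenerate")
  }) |> bind_rows()
}

#' Plot shared-clonotype recovery curves
#'
#' @param curves One or more stacked recovery curves; a `seed` column, if
#'   present, draws one line per replicate.
#' @return A ggplot object.
#' @export
plot_recovery <- function(curves) {
  grp <- if ("seed" %in% names(curves)) factor(curves$seed) else factor(1)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$proportion,
                               y = .data$shared_with_rna, group = grp)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "fraction of IR-seq reads kept",
                  y = "clonotypes shared with RNA-seq",
                  title = "Shared-clonotype recovery under downsampling")
}
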