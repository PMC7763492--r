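# Mapping-quality diagnostics: support-stratified Kolmogorov-Smirnov
# comparisons and PCA + two-cluster low/high-quality classification.

#' Group clonotypes by supporting-read count
#'
#' Stratifies the clonotypes of one sample by their number of supporting
#' reads; counts at or above `cap` are pooled into a single top bin. Each
#' clonotype contributes one scalar quality score, the mean of its quality
#' feature vector.
#'
#' @param x A non-empty clonotype tibble with at least one quality feature
#'   column (`q_` prefix).
#' @param cap Supports `>= cap` are pooled into the top bin (integer >= 2).
#' @return A tibble `clonotype_key`, `read_count`, `support_group` (factor
#'   with levels `"1"`, ..., `"<cap>+"`), `quality`.
#' @export
group_by_support <- function(x, cap = 10L) {
  check_clonotype_tbl(x, require_quality = TRUE)
  cap <- check_scalar_int(cap, 2L, "cap")
  if (nrow(x) == 0L) {
    abort("Cannot stratify an empty sample by read support.",
          class = "repfilter_argument_error")
  }
  qc <- quality_cols(x)
  lev <- c(as.character(seq_len(cap - 1L)), paste0(cap, "+"))
  support <- pmin(x$read_count, cap)
  tibble(
    clonotype_key = x$cdr3_aa,
    read_count = x$read_count,
    support_group = factor(lev[support], levels = lev),
    quality = rowMeans(x[, qc, drop = FALSE])
  )
}

ks_pair <- function(a, b) {
  k <- suppressWarnings(ks.test(a, b))
  c(statistic = unname(k$statistic), p_value = unname(k$p.value))
}

ks_family <- function(groups, pairs, alpha, adjust) {
  res <- purrr::map(pairs, function(p) {
    qa <- groups$quality[groups$support_group == p[[1L]]]
    qb <- groups$quality[groups$support_group == p[[2L]]]
    if (length(qa) < 2L || length(qb) < 2L) {
      warn(sprintf("Comparison %s vs %s skipped: fewer than 2 observations.",
                   p[[1L]], p[[2L]]))
      return(NULL)
    }
    k <- ks_pair(qa, qb)
    tibble(group_a = p[[1L]], group_b = p[[2L]],
           n_a = length(qa), n_b = length(qb),
           statistic = k[["statistic"]], p_value = k[["p_value"]])
  }) |> bind_rows()
  if (nrow(res) == 0L) {
    return(res)
  }
  res |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = adjust),
           significant = .data$p_adjusted < alpha)
}

#' Compare the singleton quality distribution with every other support group
#'
#' Two-sample Kolmogorov-Smirnov comparison of the quality scores of
#' singleton clonotypes against each multi-read support group, with
#' multiple-testing adjustment across the family. In clean data the
#' singleton group is expected to stand out — it is where sequencing and
#' mapping artifacts accumulate — while multi-read groups share one quality
#' distribution.
#'
#' @param groups Output of [group_by_support()].
#' @param alpha Significance level applied to adjusted p-values.
#' @param adjust Adjustment method: `"BH"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @return A tibble with one row per comparison: group labels, sizes, KS
#'   `statistic` (the supremum of the absolute ECDF difference), `p_value`,
#'   `p_adjusted`, `significant`. Undersized groups are skipped with a
#'   warning.
#' @export
ks_singleton_vs_groups <- function(groups, alpha = 0.05,
                                   adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  present <- levels(droplevels(groups$support_group))
  if (!"1" %in% present) {
    abort("No singleton group present.", class = "repfilter_argument_error")
  }
  pairs <- purrr::map(setdiff(present, "1"), ~ c("1", .x))
  if (!length(pairs)) {
    abort("No multi-read group to compare the singletons against.",
          class = "repfilter_argument_error")
  }
  ks_family(groups, pairs, alpha, adjust)
}

#' Compare adjacent multi-read support groups
#'
#' Two-sample Kolmogorov-Smirnov comparisons between each pair of adjacent
#' multi-read support groups (2 vs 3, 3 vs 4, ..., last vs pooled top bin),
#' adjusted as one family. Complements [ks_singleton_vs_groups()]: when the
#' singleton stratum is the only contaminated one, these comparisons should
#' all be non-significant.
#'
#' @inheritParams ks_singleton_vs_groups
#' @return As [ks_singleton_vs_groups()].
#' @export
ks_adjacent_groups <- function(groups, alpha = 0.05,
                               adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  present <- setdiff(levels(droplevels(groups$support_group)), "1")
  if (length(present) < 2L) {
    abort("Need at least two multi-read groups for adjacent comparisons.",
          class = "repfilter_argument_error")
  }
  pairs <- purrr::map(seq_len(length(present) - 1L),
                      ~ c(present[.x], present[.x + 1L]))
  ks_family(groups, pairs, alpha, adjust)
}

#' Principal components of clonotype quality features
#'
#' Projects the per-clonotype mapping-quality feature vectors onto their
#' first two principal components (features centred and scaled to unit
#' variance; features without variance are dropped with a warning). With a
#' single usable feature the first component is the scaled feature itself
#' and PC2 is fixed at zero (flagged).
#'
#' @param x A clonotype tibble with at least 3 rows and quality features.
#' @return An object of class `quality_clust` holding the per-clonotype
#'   scores (`PC1`, `PC2`), the scalar quality, explained variances and the
#'   feature matrix. Labels are filled in by [classify_quality()].
#' @export
quality_pca <- function(x) {
  check_clonotype_tbl(x, require_quality = TRUE)
  if (nrow(x) < 3L) {
    abort("Need at least 3 clonotypes for a quality PCA.",
          class = "repfilter_argument_error")
  }
  qc <- quality_cols(x)
  feats <- as.matrix(x[, qc, drop = FALSE])
  keep <- apply(feats, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) {
    abort("All quality features are constant; PCA is degenerate.",
          class = "repfilter_degenerate_error")
  }
  if (any(!keep)) {
    warn(sprintf("Dropping constant quality feature(s): %s.",
                 paste(qc[!keep], collapse = ", ")))
  }
  usable <- feats[, keep, drop = FALSE]
  pc2_degenerate <- ncol(usable) < 2L
  if (pc2_degenerate) {
    z <- scale(usable)
    scores <- cbind(PC1 = z[, 1L], PC2 = 0)
    var_explained <- c(1, 0)
    rotation <- matrix(1, 1L, 1L, dimnames = list(colnames(usable), "PC1"))
  } else {
    fit <- prcomp(usable, center = TRUE, scale. = TRUE)
    scores <- fit$x[, 1:2, drop = FALSE]
    var_explained <- (fit$sdev^2 / sum(fit$sdev^2))[1:2]
    rotation <- fit$rotation
  }
  structure(
    list(
      scores = tibble(
        clonotype_key = x$cdr3_aa,
        read_count = x$read_count,
        quality = rowMeans(feats),
        PC1 = unname(scores[, 1L]),
        PC2 = unname(scores[, 2L])
      ),
      features = feats,
      var_explained = var_explained,
      rotation = rotation,
      pc2_degenerate = pc2_degenerate,
      labels_filled = FALSE,
      seed = NULL,
      cluster_means = NULL
    ),
    class = "quality_clust"
  )
}

#' Classify clonotypes into low- and high-quality clusters
#'
#' Partitions the clonotypes into two clusters by k-means (k = 2) on their
#' first two quality principal components. The cluster with the lower mean
#' scalar quality is labelled `"low"`, which makes the labelling invariant
#' to cluster-index permutation; the partition itself is deterministic
#' given `seed`.
#'
#' @param classification A `quality_clust` object from [quality_pca()].
#' @param seed Integer seed controlling the k-means initialisation.
#' @return The `quality_clust` object with a `label` column (`"low"` /
#'   `"high"`) added to its scores and per-cluster feature means filled in.
#' @export
classify_quality <- function(classification, seed = 1L) {
  if (!inherits(classification, "quality_clust")) {
    abort("`classification` must come from quality_pca().",
          class = "repfilter_argument_error")
  }
  seed <- check_scalar_int(seed, -.Machine$integer.max, "seed")
  sc <- classification$scores
  if (nrow(sc) < 2L) {
    abort("Need at least 2 clonotypes to classify.",
          class = "repfilter_argument_error")
  }
  pts <- cbind(sc$PC1, sc$PC2)
  if (nrow(unique(pts)) < 2L) {
    abort("All clonotypes project to one point; clustering is degenerate.",
          class = "repfilter_degenerate_error")
  }
  km <- withr::with_seed(seed,
    kmeans(pts, centers = 2L, nstart = 10L, iter.max = 100L))
  mean_q <- tapply(sc$quality, km$cluster, mean)
  low_cluster <- as.integer(names(which.min(mean_q)))
  sc$label <- ifelse(km$cluster == low_cluster, "low", "high")
  classification$scores <- sc
  classification$labels_filled <- TRUE
  classification$seed <- seed
  classification$cluster_means <- rbind(
    low = colMeans(classification$features[km$cluster == low_cluster, ,
                                           drop = FALSE]),
    high = colMeans(classification$features[km$cluster != low_cluster, ,
                                            drop = FALSE])
  )
  classification
}

#' Low-quality composition by support group
#'
#' For every supporting-read bin, the fraction of clonotypes labelled
#' low-quality. Relates the quality clustering back to read support: when
#' artifacts drive the low cluster, the singleton bin carries almost all of
#' it.
#'
#' @param classification A labelled `quality_clust` (see
#'   [classify_quality()]).
#' @param groups Output of [group_by_support()] on the same sample.
#' @return A tibble `support_group`, `n`, `n_low`, `frac_low`.
#' @export
low_quality_composition <- function(classification, groups) {
  if (!inherits(classification, "quality_clust") ||
      !isTRUE(classification$labels_filled)) {
    abort("`classification` must be labelled by classify_quality() first.",
          class = "repfilter_argument_error")
  }
  sc <- classification$scores
  if (nrow(sc) != nrow(groups) ||
      !setequal(sc$clonotype_key, groups$clonotype_key)) {
    abort("`classification` and `groups` cover different clonotype sets.",
          class = "repfilter_argument_error")
  }
  left_join(groups, sc[, c("clonotype_key", "label")],
            by = "clonotype_key") |>
    group_by(.data$support_group, .drop = FALSE) |>
    summarise(n = dplyr::n(), n_low = sum(.data$label == "low"),
              .groups = "drop") |>
    filter(.data$n > 0L) |>
    mutate(frac_low = .data$n_low / .data$n)
}

#' @export
print.quality_clust <- function(x, ...) {
  cat(sprintf("Quality PCA of %d clonotypes (PC1 %.1f%%, PC2 %.1f%% variance)\n",
              nrow(x$scores), 100 * x$var_explained[1L],
              100 * x$var_explained[2L]))
  if (isTRUE(x$labels_filled)) {
    cat(sprintf("  low-quality: %d (%.1f%%), seed %d\n",
                sum(x$scores$label == "low"),
                100 * mean(x$scores$label == "low"), x$seed))
  } else {
    cat("  unlabelled; run classify_quality()\n")
  }
  invisible(x)
}

#' @rdname quality_pca
#' @param x,object A `quality_clust` object.
#' @param ... Unused.
#' @export
tidy.quality_clust <- function(x, ...) {
  x$scores
}

#' @rdname quality_pca
#' @export
glance.quality_clust <- function(x, ...) {
  sc <- x$scores
  labelled <- isTRUE(x$labels_filled)
  tibble(
    n = nrow(sc),
    var_explained_pc1 = x$var_explained[1L],
    var_explained_pc2 = x$var_explained[2L],
    frac_low = if (labelled) mean(sc$label == "low") else NA_real_,
    mean_quality_low = if (labelled) mean(sc$quality[sc$label == "low"]) else NA_real_,
    mean_quality_high = if (labelled) mean(sc$quality[sc$label == "high"]) else NA_real_
  )
}

#' @rdname quality_pca
#' @export
autoplot.quality_clust <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (isTRUE(object$labels_filled)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                                 alpha = 0.4, size = 0.8)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$quality),
                                 alpha = 0.4, size = 0.8)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1L]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2L]),
    colour = NULL,
    title = "Clonotype mapping-quality principal components"
  )
}
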