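quality_tbl <- function(counts, q = NULL) {
  n <- length(counts)
  tibble::tibble(
    cdr3_aa = paste0("C", sprintf("%03d", seq_len(n)), "F"),
    read_count = as.integer(counts),
    q_a = q %||% runif(n, 20, 70)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("support grouping partitions the clonotypes and pools at the cap", {
  g <- group_by_support(quality_tbl(c(1, 1, 2, 5)), cap = 4)
  expect_equal(as.vector(table(g$support_group)[c("1", "2", "4+")]),
               c(2L, 1L, 1L))

  g <- group_by_support(quality_tbl(rep(1, 5)), cap = 10)
  expect_true(all(g$support_group == "1"))

  withr::local_seed(31)
  for (i in 1:15) {
    s <- random_sample_tbl()
    g <- group_by_support(s, cap = 5)
    expect_equal(nrow(g), nrow(s))
    expect_equal(sum(table(g$support_group)), nrow(s))
  }
  expect_error(group_by_support(quality_tbl(1), cap = 1),
               class = "repfilter_argument_error")
})

test_that("the scalar quality score is the mean of the feature vector", {
  s <- quality_tbl(c(1, 2))
  s$q_b <- c(10, 20)
  g <- group_by_support(s, cap = 3)
  expect_equal(g$quality, rowMeans(cbind(s$q_a, s$q_b)))
})

test_that("KS comparisons reach their exact limits and match the ECDF oracle", {
  vals <- runif(30, 0, 1)
  g <- make_groups(list(`1` = vals, `2` = vals))
  k <- ks_singleton_vs_groups(g)
  expect_equal(k$statistic, 0)
  expect_equal(k$p_value, 1)

  g <- make_groups(list(`1` = runif(25, 0, 1), `2` = runif(25, 2, 3)))
  k <- ks_singleton_vs_groups(g)
  expect_equal(k$statistic, 1)
  expect_true(k$significant)

  withr::local_seed(32)
  for (i in 1:25) {
    a <- round(runif(sample(5:40, 1)), 3)
    b <- round(runif(sample(5:40, 1)), 3)
    k <- ks_singleton_vs_groups(make_groups(list(`1` = a, `2` = b)))
    expect_equal(k$statistic, ks_stat_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("KS statistics are invariant under strictly monotone transforms", {
  withr::local_seed(33)
  for (i in 1:10) {
    a <- runif(20, 1, 5)
    b <- runif(25, 1, 5)
    k1 <- ks_singleton_vs_groups(make_groups(list(`1` = a, `2` = b)))
    k2 <- ks_singleton_vs_groups(make_groups(list(`1` = exp(a), `2` = exp(b))))
    expect_equal(k1$statistic, k2$statistic)
  }
})

test_that("the KS family requires singletons and skips undersized groups", {
  g <- make_groups(list(`2` = runif(10), `3` = runif(10)))
  expect_error(ks_singleton_vs_groups(g), class = "repfilter_argument_error")

  g <- make_groups(list(`1` = runif(10), `2` = runif(1), `3` = runif(10)))
  expect_warning(k <- ks_singleton_vs_groups(g), "skipped")
  expect_equal(k$group_b, "3")

  adj <- ks_adjacent_groups(make_groups(list(`2` = runif(10),
                                             `3` = runif(10),
                                             `4` = runif(10))))
  expect_equal(nrow(adj), 2L)
  expect_true(all(adj$p_adjusted >= adj$p_value))
})

test_that("quality PCA matches an independent eigendecomposition", {
  withr::local_seed(34)
  n <- 60
  s <- quality_tbl(rep(2, n))
  s$q_a <- rnorm(n, 50, 6)
  s$q_b <- 0.7 * s$q_a + rnorm(n, 0, 3)
  s$q_c <- rnorm(n, 30, 2)
  qc <- quality_pca(s)

  z <- scale(cbind(s$q_a, s$q_b, s$q_c))
  ev <- eigen(stats::cov(z))
  proj <- z %*% ev$vectors[, 1:2]
  align <- function(a, b) if (sum(a * b) < 0) -b else b
  expect_equal(qc$scores$PC1, align(qc$scores$PC1, proj[, 1]),
               tolerance = 1e-8)
  expect_equal(qc$scores$PC2, align(qc$scores$PC2, proj[, 2]),
               tolerance = 1e-8)
  expect_gte(qc$var_explained[1], qc$var_explained[2])
})

test_that("degenerate quality matrices are flagged or rejected", {
  s <- quality_tbl(rep(1, 5), q = rep(3, 5))
  expect_error(quality_pca(s), class = "repfilter_degenerate_error")

  # one informative feature: PC2 pinned at zero
  s <- quality_tbl(rep(1, 5), q = c(1, 2, 3, 4, 5))
  s$q_b <- 7
  expect_warning(qc <- quality_pca(s), "constant")
  expect_true(qc$pc2_degenerate)
  expect_true(all(qc$scores$PC2 == 0))

  # collinear two-feature case: PC2 numerically zero
  s <- quality_tbl(rep(1, 6), q = 1:6)
  s$q_b <- 2 * s$q_a + 1
  qc <- quality_pca(s)
  expect_true(all(abs(qc$scores$PC2) < 1e-8))
})

test_that("two-cluster classification recovers separated clouds", {
  withr::local_seed(35)
  n <- 200
  lowq <- rnorm(n / 2, 20, 2)
  highq <- rnorm(n / 2, 60, 2)
  s <- quality_tbl(rep(2, n), q = c(lowq, highq))
  s$q_b <- c(rnorm(n / 2, 25, 2), rnorm(n / 2, 55, 2))
  qc <- classify_quality(quality_pca(s), seed = 7)
  truth <- rep(c("low", "high"), each = n / 2)
  expect_gte(mean(qc$scores$label == truth), 0.99)
  expect_lt(mean(qc$scores$quality[qc$scores$label == "low"]),
            mean(qc$scores$quality[qc$scores$label == "high"]))

  # same seed, same labels
  qc2 <- classify_quality(quality_pca(s), seed = 7)
  expect_equal(qc$scores$label, qc2$scores$label)

  g <- glance(qc)
  expect_equal(g$n, n)
  expect_equal(g$frac_low, mean(qc$scores$label == "low"))
})

test_that("classification handles duplicated points and rejects identical ones", {
  s <- quality_tbl(rep(1, 4), q = c(1, 1, 9, 9))
  s$q_b <- c(2, 2, 8, 8)
  qc <- classify_quality(quality_pca(s), seed = 1)
  expect_equal(qc$scores$label, c("low", "low", "high", "high"))

  # all clonotypes projecting to one point cannot be partitioned
  qc <- quality_pca(quality_tbl(rep(1, 4), q = c(1, 2, 8, 9)))
  qc$scores$PC1 <- 0
  qc$scores$PC2 <- 0
  expect_error(classify_quality(qc), class = "repfilter_degenerate_error")
})

test_that("low-quality composition recounts match brute force", {
  withr::local_seed(36)
  s <- random_sample_tbl(n = 40, n_quality = 2)
  g <- group_by_support(s, cap = 4)
  qc <- classify_quality(quality_pca(s), seed = 2)
  comp <- low_quality_composition(qc, g)

  lab <- setNames(qc$scores$label, qc$scores$clonotype_key)
  for (i in seq_len(nrow(comp))) {
    keys <- g$clonotype_key[g$support_group == comp$support_group[i]]
    expect_equal(comp$frac_low[i], mean(lab[keys] == "low"))
  }
  # bin-weighted mean equals the overall low fraction
  expect_equal(sum(comp$n * comp$frac_low) / sum(comp$n),
               mean(qc$scores$label == "low"))

  expect_error(low_quality_composition(qc, g[-1L, ]),
               class = "repfilter_argument_error")
})

test_that("removing singletons shrinks the low-quality fraction", {
  cfg <- small_sim_config(seed = 88)
  ir <- simulate_sample(simulate_repertoire(cfg), cfg, "IR", seed = 89)$sample
  frac_low <- function(s) {
    qc <- classify_quality(quality_pca(s), seed = 1)
    mean(qc$scores$label == "low")
  }
  expect_lt(frac_low(filter_min_reads(ir, 2)), frac_low(ir))
})
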