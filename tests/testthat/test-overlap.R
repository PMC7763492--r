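keyed_tbl <- function(keys, counts = NULL, sample_id = "S1",
                      platform = "IR") {
  tibble::tibble(sample_id = sample_id, platform = platform,
                 cdr3_aa = keys,
                 read_count = as.integer(counts %||% rep(1L, length(keys))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cross-sample sharing counts sample support correctly", {
  x <- dplyr::bind_rows(
    keyed_tbl(c("A", "B"), sample_id = "s1"),
    keyed_tbl(c("B", "C"), sample_id = "s2"),
    keyed_tbl("D", sample_id = "s3")
  )
  sh <- shared_across_samples(x, 2)
  expect_equal(sh$clonotype_key, "B")
  expect_equal(sh$n_samples, 2L)

  same <- dplyr::bind_rows(
    keyed_tbl(c("A", "B", "C"), sample_id = "s1"),
    keyed_tbl(c("A", "B", "C"), sample_id = "s2"),
    keyed_tbl(c("A", "B", "C"), sample_id = "s3")
  )
  sh <- shared_across_samples(same, 2)
  expect_setequal(sh$clonotype_key, c("A", "B", "C"))
  expect_true(all(sh$n_samples == 3L))

  expect_error(shared_across_samples(x, 1), class = "repfilter_argument_error")
})

test_that("sharing matches a hash-count oracle and nests across thresholds", {
  withr::local_seed(21)
  for (i in 1:10) {
    cohort <- purrr::map(1:6, ~ random_sample_tbl(sample_id = paste0("s", .x)))
    x <- dplyr::bind_rows(cohort)
    tallies <- new.env()
    for (s in cohort) {
      for (k in unique(s$cdr3_aa)) {
        assign(k, (get0(k, tallies, ifnotfound = 0L)) + 1L, tallies)
      }
    }
    for (m in 2:3) {
      sh <- shared_across_samples(x, m)
      oracle <- Filter(function(k) get(k, tallies) >= m, ls(tallies))
      expect_setequal(sh$clonotype_key, oracle)
    }
    expect_true(all(shared_across_samples(x, 3)$clonotype_key %in%
                      shared_across_samples(x, 2)$clonotype_key))
  }
})

test_that("paired sharing is the symmetric key intersection", {
  ir <- keyed_tbl(c("A", "B"), c(3, 2))
  rna <- keyed_tbl(c("B", "C"), c(1, 4), platform = "RNA")
  sh <- paired_shared(ir, rna)
  expect_equal(sh$clonotype_key, "B")
  expect_equal(sh$ir_reads, 2L)
  expect_equal(sh$rna_reads, 1L)

  expect_equal(nrow(paired_shared(keyed_tbl("A"), keyed_tbl("Z"))), 0L)

  withr::local_seed(22)
  for (i in 1:10) {
    a <- random_sample_tbl()
    b <- random_sample_tbl(platform = "RNA")
    expect_setequal(paired_shared(a, b)$clonotype_key,
                    paired_shared(b, a)$clonotype_key)
  }
})

test_that("retention under filtering matches the worked example and an oracle", {
  ir <- keyed_tbl(c("A", "B"), c(5, 1))
  rna <- keyed_tbl(c("A", "B", "C"), c(3, 1, 2), platform = "RNA")
  r <- retention_under_filter(ir, rna, 2)
  expect_equal(r$shared_before, 2L)
  expect_equal(r$shared_after, 1L)
  expect_equal(r$eliminated_fraction, 0.5)

  expect_equal(retention_under_filter(ir, rna, 1)$eliminated_fraction, 0)

  withr::local_seed(23)
  for (i in 1:15) {
    a <- random_sample_tbl()
    b <- random_sample_tbl(platform = "RNA")
    t <- sample(1:4, 1L)
    r <- retention_under_filter(a, b, t)
    before <- length(intersect(a$cdr3_aa, b$cdr3_aa))
    after <- length(intersect(a$cdr3_aa[a$read_count >= t],
                              b$cdr3_aa[b$read_count >= t]))
    expect_equal(r$shared_before, before)
    expect_equal(r$shared_after, after)
    # monotone in the threshold
    r2 <- retention_under_filter(a, b, t + 1L)
    expect_lte(r2$shared_after, r$shared_after)
  }

  none <- retention_under_filter(keyed_tbl("A"), keyed_tbl("Z"))
  expect_true(is.na(none$eliminated_fraction))
})

test_that("shared-frequency correlation recovers exact limits and the formula", {
  # identical repertoires: frequencies equal on both axes, r = 1
  a <- keyed_tbl(c("A", "B", "C"), c(6, 3, 1))
  b <- keyed_tbl(c("A", "B", "C"), c(6, 3, 1), platform = "RNA")
  r <- shared_frequency_correlation(list(list(ir = a, rna = b)), min_reads = 1)
  expect_equal(r$estimate, 1)

  # two shared clonotypes ranked oppositely on the two platforms: r = -1
  a <- keyed_tbl(c("A", "B"), c(10, 20))
  b <- keyed_tbl(c("A", "B"), c(20, 10), platform = "RNA")
  r <- shared_frequency_correlation(list(list(ir = a, rna = b)), min_reads = 1)
  expect_equal(r$estimate, -1)

  withr::local_seed(24)
  for (i in 1:10) {
    pairs <- purrr::map(1:3, ~ list(
      ir = random_sample_tbl(n = 20, sample_id = paste0("s", .x)),
      rna = random_sample_tbl(n = 20, sample_id = paste0("s", .x),
                              platform = "RNA")
    ))
    # force overlap
    for (j in seq_along(pairs)) {
      pairs[[j]]$rna$cdr3_aa[1:10] <- pairs[[j]]$ir$cdr3_aa[1:10]
    }
    r <- tryCatch(shared_frequency_correlation(pairs, min_reads = 1),
                  repfilter_degenerate_error = function(e) NULL)
    if (is.null(r)) next
    expect_equal(r$estimate,
                 pearson_oracle(r$points$freq_ir, r$points$freq_rna),
                 tolerance = 1e-12)
    expect_s3_class(tidy(r), "tbl_df")
    expect_equal(glance(r)$n_points, nrow(r$points))
  }

  expect_error(
    shared_frequency_correlation(list(list(ir = keyed_tbl("A"),
                                           rna = keyed_tbl("Z")))),
    class = "repfilter_degenerate_error")
})

test_that("error-free deep capture eliminates almost nothing when filtered", {
  cfg <- sim_config(n_true_clones = 500L, ir_depth = 100000L,
                    rna_depth = 100000L, error_rate = 0, seed = 77)
  rep <- simulate_repertoire(cfg)
  ir <- simulate_sample(rep, cfg, "IR", seed = 78)$sample
  rna <- simulate_sample(rep, cfg, "RNA", depth = 100000L, seed = 79)$sample
  r <- retention_under_filter(ir, rna, min_reads = 2)
  expect_lte(r$eliminated_fraction, 0.02)
})
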