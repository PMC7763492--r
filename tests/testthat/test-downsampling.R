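ds_tbl <- function(counts) {
  tibble::tibble(cdr3_aa = paste0("C", sprintf("%03d", seq_along(counts)), "F"),
                 read_count = as.integer(counts), q_x = seq_along(counts))
}

test_that("thinning conserves the target read total exactly", {
  s <- ds_tbl(c(10, 30, 60))
  expect_identical(downsample_counts(s, 1, seed = 1), s)

  withr::local_seed(61)
  for (i in 1:25) {
    s <- ds_tbl(sample.int(50, sample(2:20, 1), replace = TRUE))
    p <- runif(1, 0.05, 0.95)
    d <- downsample_counts(s, p, seed = i)
    expect_equal(sum(d$read_count), floor(p * sum(s$read_count)))
    expect_true(all(d$read_count >= 1))
    m <- match(d$cdr3_aa, s$cdr3_aa)
    expect_true(all(d$read_count <= s$read_count[m]))
    expect_equal(d$q_x, s$q_x[m]) # carried features untouched
  }

  expect_warning(e <- downsample_counts(ds_tbl(1), 0.5, seed = 1),
                 "0 reads")
  expect_equal(nrow(e), 0L)
  expect_error(downsample_counts(ds_tbl(1), 1.5),
               class = "repfilter_argument_error")
  expect_error(downsample_counts(ds_tbl(1), 0),
               class = "repfilter_argument_error")
})

test_that("thinning is reproducible given the seed", {
  s <- ds_tbl(c(100, 50, 25))
  a <- downsample_counts(s, 0.4, seed = 9)
  b <- downsample_counts(s, 0.4, seed = 9)
  expect_identical(a, b)
})

test_that("per-clonotype draws match hypergeometric moments", {
  s <- ds_tbl(c(800, 200))
  draws <- vapply(1:200, function(seed) {
    d <- downsample_counts(s, 0.5, seed = seed)
    sum(d$read_count[d$cdr3_aa == s$cdr3_aa[1]])
  }, numeric(1))
  v <- 500 * 0.8 * 0.2 * (500 / 999) # hypergeometric variance
  se <- sqrt(v / length(draws))
  expect_lt(abs(mean(draws) - 400), 3 * se)
})

test_that("recovery curves are exactly nested-monotone and hit the endpoints", {
  withr::local_seed(62)
  rna <- random_sample_tbl(n = 15, platform = "RNA")
  for (i in 1:25) {
    ir <- ds_tbl(sample.int(40, 30, replace = TRUE))
    ir$cdr3_aa[1:5] <- rna$cdr3_aa[1:5]
    rc <- recovery_curve(ir, rna, proportions = c(0.1, 0.3, 0.6, 1),
                         seed = i)
    expect_true(all(diff(rc$unique_clonotypes) >= 0))
    expect_true(all(diff(rc$shared_with_rna) >= 0))
    expect_true(all(rc$shared_with_rna <= rc$unique_clonotypes))
    full <- rc[rc$proportion == 1, ]
    expect_equal(full$unique_clonotypes, nrow(ir))
    expect_equal(full$shared_with_rna, nrow(paired_shared(ir, rna)))
    expect_equal(rc$total_reads, floor(rc$proportion * sum(ir$read_count)))
  }

  empty_rna <- rna[0L, ]
  rc <- recovery_curve(ds_tbl(c(5, 5)), empty_rna, proportions = c(0.5, 1),
                       seed = 1)
  expect_true(all(rc$shared_with_rna == 0))

  expect_error(recovery_curve(ds_tbl(c(2, 3)), rna, proportions = c(0.5, 0.2)),
               class = "repfilter_argument_error")
})

test_that("independent (non-nested) thinning still conserves totals", {
  withr::local_seed(63)
  ir <- ds_tbl(sample.int(40, 25, replace = TRUE))
  rna <- random_sample_tbl(n = 10, platform = "RNA")
  rc <- recovery_curve(ir, rna, proportions = c(0.2, 0.5, 0.9), seed = 4,
                       nested = FALSE)
  expect_equal(rc$total_reads, floor(c(0.2, 0.5, 0.9) * sum(ir$read_count)))
})

test_that("depth significance tests flag nothing under the null", {
  curves <- tidyr::expand_grid(seed = 1:5, proportion = c(0.1, 0.5)) |>
    dplyr::mutate(shared_with_rna = 10)
  sig <- recovery_significance(curves)
  expect_true(all(sig$degenerate))
  expect_false(any(sig$significant))

  withr::local_seed(64)
  curves <- tidyr::expand_grid(seed = 1:10, proportion = c(0.1, 0.5)) |>
    dplyr::mutate(shared_with_rna = rpois(dplyr::n(), 50))
  sig <- recovery_significance(curves)
  a <- curves$shared_with_rna[curves$proportion == 0.1]
  b <- curves$shared_with_rna[curves$proportion == 0.5]
  o <- welch_oracle(a, b)
  expect_equal(sig$t_statistic, o$t, tolerance = 1e-10)
  expect_equal(sig$df, o$df, tolerance = 1e-10)

  expect_error(recovery_significance(curves[curves$seed == 1, ]),
               class = "repfilter_argument_error")
})
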