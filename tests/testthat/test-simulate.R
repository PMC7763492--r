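test_that("repertoire generation is deterministic with valid frequencies", {
  cfg <- small_sim_config(seed = 3)
  rep1 <- simulate_repertoire(cfg)
  rep2 <- simulate_repertoire(cfg)
  expect_identical(rep1, rep2)
  expect_equal(sum(rep1$frequency), 1)
  expect_false(any(duplicated(rep1$cdr3_aa)))
  expect_true(all(nchar(rep1$cdr3_aa) %in% 8:20))

  single <- simulate_repertoire(sim_config(n_true_clones = 1, seed = 1))
  expect_equal(single$frequency, 1)

  expect_error(sim_config(power_exponent = 1),
               class = "repfilter_argument_error")
  expect_error(sim_config(error_rate = 1),
               class = "repfilter_argument_error")
})

test_that("power-law repertoires have rank-frequency slope near -1", {
  cfg <- sim_config(n_true_clones = 10000L, power_exponent = 2, seed = 8)
  rep <- simulate_repertoire(cfg)
  f <- sort(rep$frequency, decreasing = TRUE)
  ranks <- 10:1000 # central ranks, away from the truncated extremes
  fit <- stats::lm(log(f[ranks]) ~ log(ranks))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.1)
})

test_that("error-free sequencing yields only true clonotypes", {
  cfg <- small_sim_config(seed = 4, error_rate = 0)
  rep <- simulate_repertoire(cfg)
  out <- simulate_sample(rep, cfg, "IR", seed = 11)
  expect_false(any(out$truth$is_artifact))
  expect_true(all(out$sample$cdr3_aa %in% rep$cdr3_aa))
  expect_equal(sum(out$sample$read_count), cfg$ir_depth)

  empty <- simulate_sample(rep, cfg, "IR", depth = 0, seed = 11)
  expect_equal(nrow(empty$sample), 0L)
})

test_that("artifact reads appear at the configured rate, all as singletons", {
  cfg <- small_sim_config(seed = 5)
  rep <- simulate_repertoire(cfg)
  art_fracs <- vapply(1:20, function(s) {
    out <- simulate_sample(rep, cfg, "IR", seed = 100 + s)
    art <- out$truth[out$truth$is_artifact, ]
    counts <- out$sample$read_count[match(art$clonotype_key,
                                          out$sample$cdr3_aa)]
    expect_gte(mean(counts == 1L), 0.95)
    sum(counts) / sum(out$sample$read_count)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (20 * cfg$ir_depth))
  expect_lt(abs(mean(art_fracs) - 0.05), 3 * se + 0.001)
})

test_that("truth tables carry a complete frequency decomposition", {
  cfg <- small_sim_config(seed = 6)
  out <- simulate_sample(simulate_repertoire(cfg), cfg, "RNA", seed = 21)
  truth <- out$truth
  expect_equal(sum(truth$true_frequency[!truth$is_artifact]), 1)
  expect_true(all(truth$true_frequency[truth$is_artifact] == 0))
  # every observed sample clonotype is accounted for in the truth
  expect_true(all(out$sample$cdr3_aa %in% truth$clonotype_key))
})

test_that("sample quality features are summaries of per-read draws", {
  cfg <- small_sim_config(seed = 7)
  out <- simulate_sample(simulate_repertoire(cfg), cfg, "IR", seed = 31)
  s <- out$sample
  expect_true(all(s$q_min <= s$q_mean & s$q_mean <= s$q_max))
  expect_true(all(s$q_sd >= 0))
  expect_true(all(s$q_sd[s$read_count == 1L] == 0))

  # fewer configured features are honoured
  cfg2 <- small_sim_config(seed = 7, n_quality_features = 2)
  out2 <- simulate_sample(simulate_repertoire(cfg2), cfg2, "IR", seed = 31)
  expect_setequal(grep("^q_", names(out2$sample), value = TRUE),
                  c("q_mean", "q_min"))
})

test_that("paired samples share one repertoire and reproduce bitwise", {
  cfg <- small_sim_config(seed = 9)
  p1 <- simulate_pair(cfg, sample_id = "P1")
  p2 <- simulate_pair(cfg, sample_id = "P1")
  expect_identical(p1, p2)
  expect_gt(nrow(p1$ir), 0)
  expect_gt(nrow(p1$rna), 0)
  # both platforms' observed clonotypes resolve against their truth tables
  expect_true(all(p1$ir$cdr3_aa %in% p1$truth$ir$clonotype_key))
  expect_true(all(p1$rna$cdr3_aa %in% p1$truth$rna$clonotype_key))
  # the non-artifact truth rows are the same latent repertoire on both sides
  expect_identical(p1$truth$ir$clonotype_key[!p1$truth$ir$is_artifact],
                   p1$truth$rna$clonotype_key[!p1$truth$rna$is_artifact])
})

test_that("cohorts recover the shared clone pool across samples", {
  cfg <- small_sim_config(seed = 10, shared_clone_fraction = 0.1)
  cohort <- simulate_cohort(cfg, n_samples = 4)
  pool <- attr(cohort, "pool")
  expect_equal(length(pool), round(0.1 * cfg$n_true_clones))
  stacked <- purrr::map(cohort, "ir") |> dplyr::bind_rows()
  sh <- shared_across_samples(stacked, 2)
  expect_gte(mean(pool %in% sh$clonotype_key), 0.8)
})
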