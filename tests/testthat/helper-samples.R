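# Small random clonotype tables for property tests, built independently of
# the package's own simulator.

random_keys <- function(n) {
  len <- sample(6:12, n, replace = TRUE)
  vapply(len, function(l) {
    paste0("C", paste(sample(LETTERS[1:20], l, replace = TRUE),
                      collapse = ""), "F")
  }, "")
}

random_sample_tbl <- function(n = NULL, max_count = 20L, n_quality = 2L,
                              genes = TRUE, sample_id = "S1",
                              platform = "IR") {
  if (is.null(n)) n <- sample(1:30, 1L)
  keys <- unique(random_keys(3L * n))[seq_len(n)]
  # counts skewed so singletons are common
  counts <- ifelse(runif(n) < 0.5, 1L, sample.int(max_count, n, replace = TRUE))
  tbl <- tibble::tibble(
    sample_id = sample_id, platform = platform,
    cdr3_aa = keys, read_count = as.integer(counts)
  )
  if (genes) {
    tbl$v_gene <- paste0("TRBV", sample(1:8, n, replace = TRUE))
    tbl$j_gene <- paste0("TRBJ", sample(1:4, n, replace = TRUE))
  }
  for (k in seq_len(n_quality)) {
    tbl[[paste0("q_f", k)]] <- round(runif(n, 0, 60), 4)
  }
  tbl
}

# Independent double-loop ECDF supremum oracle for the two-sample KS
# statistic.
ks_stat_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  d <- 0
  for (g in grid) {
    d <- max(d, abs(mean(a <= g) - mean(b <= g)))
  }
  d
}

# Closed-form Welch statistic and Welch-Satterthwaite degrees of freedom.
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  sa <- va / length(a)
  sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Textbook covariance-formula Pearson correlation.
pearson_oracle <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# A quick support-group tibble from explicit value lists.
make_groups <- function(values_by_group, cap = 10L) {
  lev <- c(as.character(seq_len(cap - 1L)), paste0(cap, "+"))
  purrr::imap(values_by_group, function(vals, g) {
    tibble::tibble(
      clonotype_key = paste0(g, "_", seq_along(vals)),
      read_count = as.integer(gsub("[^0-9]", "", g)),
      support_group = factor(as.character(g), levels = lev),
      quality = vals
    )
  }) |> dplyr::bind_rows()
}

# Reduced-scale simulator configuration for fast unit tests.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_true_clones = 2000L, ir_depth = 50000L, rna_depth = 300L,
             seed = seed, ...)
}
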