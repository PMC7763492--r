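# Welch two-sample comparison with explicit handling of the zero-variance
# degenerate case (stats::t.test errors on essentially constant data).
# Returns t, Welch-Satterthwaite df, two-sided p and a degeneracy flag.
welch_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Welch comparison needs at least 2 observations per group.",
          class = "repfilter_argument_error")
  }
  va <- var(a)
  vb <- var(b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(
      t_statistic = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
      df = NA_real_,
      p_value = if (equal) 1 else 0,
      degenerate = TRUE
    ))
  }
  fit <- stats::t.test(a, b, var.equal = FALSE)
  tibble(t_statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value, degenerate = FALSE)
}
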