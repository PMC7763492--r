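# Internal validation helpers for clonotype tables.
#
# A clonotype table is an ordinary tibble/data.frame with one row per
# clonotype: `cdr3_aa` (character, non-empty), `read_count` (positive
# integer), optional `cdr3_nt`, `v_gene`, `d_gene`, `j_gene`, optional
# metadata `sample_id`/`platform`, and zero or more numeric mapping-quality
# feature columns prefixed `q_` (fixed set per table).

quality_cols <- function(x) {
  grep("^q_", names(x), value = TRUE)
}

check_clonotype_tbl <- function(x, require_quality = FALSE,
                                arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of clonotypes.", arg),
          class = "repfilter_validation_error")
  }
  for (col in c("cdr3_aa", "read_count")) {
    if (!col %in% names(x)) {
      abort(sprintf("`%s` is missing the mandatory column `%s`.", arg, col),
            class = "repfilter_format_error")
    }
  }
  if (nrow(x) > 0L) {
    if (anyNA(x$cdr3_aa) || any(!nzchar(x$cdr3_aa))) {
      abort(sprintf("`%s` has empty or missing `cdr3_aa` values.", arg),
            class = "repfilter_validation_error")
    }
    bad <- which(is.na(x$read_count) | x$read_count < 1)
    if (length(bad)) {
      abort(sprintf("`%s` has non-positive `read_count` at row(s) %s.",
                    arg, paste(head(bad, 5L), collapse = ", ")),
            class = "repfilter_validation_error")
    }
  }
  qc <- quality_cols(x)
  if (require_quality && !length(qc)) {
    abort(sprintf("`%s` has no quality feature columns (prefix `q_`).", arg),
          class = "repfilter_format_error")
  }
  for (col in qc) {
    if (!is.numeric(x[[col]])) {
      abort(sprintf("Quality column `%s` must be numeric.", col),
            class = "repfilter_validation_error")
    }
  }
  invisible(x)
}

check_scalar_int <- function(x, min, arg) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min),
          class = "repfilter_argument_error")
  }
  as.integer(x)
}

# Clonotype identity used for overlap operations. The default key is the
# CDR3 amino-acid sequence alone; `"vj_aa"` additionally qualifies it with
# the V and J gene calls.
clonotype_key <- function(x, key = c("aa", "vj_aa")) {
  key <- match.arg(key)
  if (key == "aa") {
    return(x$cdr3_aa)
  }
  v <- if ("v_gene" %in% names(x)) x$v_gene else NA_character_
  j <- if ("j_gene" %in% names(x)) x$j_gene else NA_character_
  paste(v, j, x$cdr3_aa, sep = "|")
}
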