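#' Column-name dialect for clonotype tables
#'
#' Clonotype tables arrive in several tab-separated dialects: AIRR
#' rearrangement field names (`junction_aa`, `duplicate_count`, `v_call`,
#' ...), MiXCR export headers (`aaSeqCDR3`, `cloneCount`, `bestVGene`, ...)
#' or the column names used by this package itself. `clonotype_col_map()`
#' returns, for every canonical column, the header names accepted for it, in
#' priority order. Supply replacements to extend or restrict the mapping.
#'
#' @param ... Named character vectors overriding individual entries, e.g.
#'   `read_count = "my_count_column"`.
#' @return A named list of character vectors.
#' @examples
#' clonotype_col_map()
#' clonotype_col_map(read_count = c("n_reads"))
#' @export
clonotype_col_map <- function(...) {
  map <- list(
    cdr3_aa    = c("cdr3_aa", "junction_aa", "aaSeqCDR3", "cdr3aa",
                   "CDR3.amino.acid.sequence"),
    read_count = c("read_count", "duplicate_count", "cloneCount", "count",
                   "Read.count", "reads"),
    cdr3_nt    = c("cdr3_nt", "junction", "nSeqCDR3", "cdr3nt",
                   "CDR3.nucleotide.sequence"),
    v_gene     = c("v_gene", "v_call", "bestVGene", "allVHitsWithScore",
                   "V.gene"),
    d_gene     = c("d_gene", "d_call", "bestDGene", "allDHitsWithScore",
                   "D.gene"),
    j_gene     = c("j_gene", "j_call", "bestJGene", "allJHitsWithScore",
                   "J.gene")
  )
  override <- list(...)
  for (nm in names(override)) {
    if (!nm %in% names(map)) {
      abort(sprintf("Unknown canonical column `%s` in column map.", nm),
            class = "repfilter_argument_error")
    }
    map[[nm]] <- as.character(override[[nm]])
  }
  map
}

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table (one row per clonotype) into the
#' canonical tibble layout used throughout the package. Rows sharing the
#' same CDR3 amino-acid sequence are merged: read counts are summed, quality
#' features are combined by read-count-weighted mean, and gene calls are
#' taken from the best-supported row. Multiple nucleotide variants of one
#' amino-acid clonotype therefore collapse to a single record.
#'
#' @param path Path to a TSV file with one header row.
#' @param platform Which assay produced the table: `"IR"` (targeted
#'   immune-repertoire sequencing) or `"RNA"` (bulk RNA-seq by-catch).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param col_map Accepted header names per canonical column, see
#'   [clonotype_col_map()].
#' @param quality_prefix Columns whose names start with this prefix are
#'   treated as numeric mapping-quality features (default `"q_"`).
#' @return A tibble with columns `sample_id`, `platform`, `cdr3_aa`,
#'   `read_count`, any of `cdr3_nt`/`v_gene`/`d_gene`/`j_gene` present in
#'   the file, and the quality feature columns. A file with only a header
#'   yields a zero-row tibble.
#' @seealso [write_clonotype_table()], [summarize_repertoire()]
#' @export
read_clonotype_table <- function(path, platform = c("IR", "RNA"),
                                 sample_id = NULL,
                                 col_map = clonotype_col_map(),
                                 quality_prefix = "q_") {
  platform <- match.arg(platform)
  if (!file.exists(path)) {
    abort(sprintf("Clonotype table `%s` does not exist.", path),
          class = "repfilter_io_error")
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)

  resolve <- function(canon) {
    hit <- intersect(col_map[[canon]], names(raw))
    if (length(hit)) hit[[1L]] else NA_character_
  }
  for (canon in c("cdr3_aa", "read_count")) {
    if (is.na(resolve(canon))) {
      abort(sprintf(
        "`%s` lacks a column for `%s` (accepted names: %s).",
        path, canon, paste(col_map[[canon]], collapse = ", ")),
        class = "repfilter_format_error")
    }
  }

  out <- tibble(
    sample_id = sample_id,
    platform = platform,
    cdr3_aa = as.character(raw[[resolve("cdr3_aa")]]),
    read_count = raw[[resolve("read_count")]]
  )
  for (canon in c("cdr3_nt", "v_gene", "d_gene", "j_gene")) {
    src <- resolve(canon)
    if (!is.na(src)) out[[canon]] <- as.character(raw[[src]])
  }
  qcols <- grep(paste0("^", quality_prefix), names(raw), value = TRUE)
  for (qc in qcols) {
    nm <- if (startsWith(qc, "q_")) qc else paste0("q_", sub(paste0("^", quality_prefix), "", qc))
    out[[nm]] <- as.numeric(raw[[qc]])
  }
  if (nrow(out) == 0L) {
    out$read_count <- integer()
    return(out)
  }

  bad <- which(is.na(out$read_count) | out$read_count < 1)
  if (length(bad)) {
    abort(sprintf("`%s` has non-positive read counts at data row(s) %s.",
                  path, paste(head(bad, 5L), collapse = ", ")),
          class = "repfilter_validation_error")
  }
  out$read_count <- as.integer(out$read_count)
  out <- merge_duplicate_clonotypes(out)
  check_clonotype_tbl(out)
  out
}

# Merge rows that share a CDR3 amino-acid key: counts summed, quality
# features read-count-weighted means, gene/nt calls from the row with the
# largest read count.
merge_duplicate_clonotypes <- function(x) {
  if (!anyDuplicated(x$cdr3_aa)) {
    return(x)
  }
  qc <- quality_cols(x)
  merged <- x |>
    group_by(.data$sample_id, .data$platform, .data$cdr3_aa) |>
    summarise(
      across(dplyr::any_of(c("cdr3_nt", "v_gene", "d_gene", "j_gene")),
             ~ .x[which.max(read_count)]),
      across(dplyr::all_of(qc),
             ~ sum(.x * read_count) / sum(read_count)),
      read_count = sum(.data$read_count),
      .groups = "drop"
    )
  merged[, names(x), drop = FALSE]
}

#' Write a clonotype table
#'
#' Writes a clonotype tibble as a tab-separated file using AIRR
#' rearrangement field names (`junction_aa`, `duplicate_count`, `v_call`,
#' `d_call`, `j_call`, `junction`); quality feature columns keep their `q_`
#' names. [read_clonotype_table()] on the result reproduces the original
#' records (keys, counts, quality features).
#'
#' @param x A clonotype tibble (see [read_clonotype_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(x, path) {
  check_clonotype_tbl(x)
  airr <- c(cdr3_aa = "junction_aa", read_count = "duplicate_count",
            cdr3_nt = "junction", v_gene = "v_call", d_gene = "d_call",
            j_gene = "j_call")
  keep <- c(intersect(names(airr), names(x)), quality_cols(x))
  out <- x[, keep, drop = FALSE]
  hit <- names(out) %in% names(airr)
  names(out)[hit] <- airr[names(out)[hit]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarise a repertoire sample
#'
#' Per-sample aggregate counts: total supporting reads, number of unique
#' clonotypes and number of singleton clonotypes (clonotypes supported by
#' exactly one read). When the input holds several samples (a `sample_id`
#' column with more than one value) one row per sample is returned.
#'
#' @param x A clonotype tibble, possibly containing several samples.
#' @return A tibble with columns `sample_id`/`platform` (when present),
#'   `total_reads`, `unique_clonotypes`, `singleton_clonotypes`. An empty
#'   sample summarises to zeros.
#' @examples
#' tbl <- tibble::tibble(cdr3_aa = c("CASSLF", "CATFFF"), read_count = c(5L, 1L))
#' summarize_repertoire(tbl)
#' @export
summarize_repertoire <- function(x) {
  check_clonotype_tbl(x)
  keys <- intersect(c("sample_id", "platform"), names(x))
  if (nrow(x) == 0L) {
    return(tibble(total_reads = 0L, unique_clonotypes = 0L,
                  singleton_clonotypes = 0L))
  }
  x |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      total_reads = sum(.data$read_count),
      unique_clonotypes = dplyr::n(),
      singleton_clonotypes = sum(.data$read_count == 1L),
      .groups = "drop"
    )
}
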