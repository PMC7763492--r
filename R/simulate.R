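# Synthetic paired IR-seq / RNA-seq repertoire generator with ground truth.
#
# The generator emulates the statistical structure the analysis assumes: a
# heavy-tailed latent clone-frequency distribution sampled deeply by IR-seq
# (millions of reads) and sparsely by bulk RNA-seq (hundreds of reads) from
# the same repertoire, plus an error process in which a sequenced read
# occasionally yields a spurious novel clonotype — a point-mutated copy of
# its source CDR3 — with degraded mapping quality. Every artifact clonotype
# is a novel key, hence a singleton, mirroring the rationale for
# singleton-read filtering.

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

quality_feature_names <- c("q_mean", "q_min", "q_max", "q_sd")

# 50 TRBV gene symbols with geometrically decaying default weights, plus
# TRBD and TRBJ tables; gene-symbol granularity only (no alleles).
default_v_genes <- c(
  "TRBV2", "TRBV3-1", "TRBV4-1", "TRBV4-2", "TRBV4-3", "TRBV5-1",
  "TRBV5-4", "TRBV5-5", "TRBV5-6", "TRBV5-8", "TRBV6-1", "TRBV6-2",
  "TRBV6-3", "TRBV6-4", "TRBV6-5", "TRBV6-6", "TRBV6-8", "TRBV6-9",
  "TRBV7-2", "TRBV7-3", "TRBV7-4", "TRBV7-6", "TRBV7-7", "TRBV7-8",
  "TRBV7-9", "TRBV9", "TRBV10-1", "TRBV10-2", "TRBV10-3", "TRBV11-1",
  "TRBV11-2", "TRBV11-3", "TRBV12-3", "TRBV12-4", "TRBV12-5", "TRBV13",
  "TRBV14", "TRBV15", "TRBV16", "TRBV18", "TRBV19", "TRBV20-1",
  "TRBV24-1", "TRBV25-1", "TRBV27", "TRBV28", "TRBV29-1", "TRBV30",
  "TRBV21-1", "TRBV23-1"
)
default_d_genes <- c("TRBD1", "TRBD2")
default_j_genes <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5",
                     "TRBJ1-6", "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4",
                     "TRBJ2-5", "TRBJ2-6", "TRBJ2-7")

gene_table <- function(genes, decay = 0.92) {
  w <- decay^(seq_along(genes) - 1)
  setNames(w / sum(w), genes)
}

#' Configuration of the paired-repertoire simulator
#'
#' Collects every tunable of the generator, with defaults chosen to emulate
#' deep targeted immune-repertoire sequencing paired with sparse bulk
#' RNA-seq TCR by-catch of one multiple-myeloma-like repertoire:
#' `ir_depth = 5e6` and `rna_depth = 500` reads; `n_true_clones = 1e5`
#' latent clones with power-law frequencies (density exponent 2, so the
#' rank-frequency slope is about -1, capped at `freq_cap` to bound the top
#' clonal fraction); an error probability `error_rate = 0.05` per read of
#' spawning a spurious novel clonotype; clonotype-level mapping-quality
#' means of N(60, 5) for true clones and a degraded N(35, 8) for artifacts
#' (both truncated at zero), with per-read noise `read_noise_sd` on top;
#' and CDR3 amino-acid lengths of 8-20 peaked near 14.
#'
#' @param n_true_clones Number of latent true clones.
#' @param frequency_law `"power_law"` (default) or `"log_normal"`.
#' @param power_exponent Density exponent of the power law (> 1).
#' @param freq_cap Upper truncation of the power-law clone sizes, in units
#'   of the smallest clone.
#' @param lognormal_sigma Log-scale standard deviation of the log-normal
#'   law.
#' @param ir_depth,rna_depth Sequenced reads per platform.
#' @param error_rate Per-read probability of yielding an artifact
#'   clonotype, in \[0, 1).
#' @param quality_true,quality_artifact Length-2 vectors `c(mean, sd)` of
#'   the clonotype-level quality distributions.
#' @param read_noise_sd Standard deviation of per-read quality noise
#'   around the clonotype-level mean.
#' @param n_quality_features Number of quality summary features per
#'   clonotype, 1-4: mean, min, max and standard deviation of its per-read
#'   qualities, in that order.
#' @param v_gene_table,d_gene_table,j_gene_table Named probability vectors
#'   over gene symbols.
#' @param cdr3_lengths,cdr3_length_weights Support and weights of the CDR3
#'   amino-acid length distribution.
#' @param shared_clone_fraction Fraction of clones drawn from a pool shared
#'   by all samples of a simulated cohort (0 disables the pool).
#' @param seed Master seed; all randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_true_clones = 100000L,
                       frequency_law = c("power_law", "log_normal"),
                       power_exponent = 2,
                       freq_cap = 1e5,
                       lognormal_sigma = 2,
                       ir_depth = 5000000L,
                       rna_depth = 500L,
                       error_rate = 0.05,
                       quality_true = c(mean = 60, sd = 5),
                       quality_artifact = c(mean = 35, sd = 8),
                       read_noise_sd = 2,
                       n_quality_features = 4L,
                       v_gene_table = gene_table(default_v_genes),
                       d_gene_table = gene_table(default_d_genes, 0.6),
                       j_gene_table = gene_table(default_j_genes, 0.85),
                       cdr3_lengths = 8:20,
                       cdr3_length_weights = stats::dnorm(8:20, 14, 2.5),
                       shared_clone_fraction = 0,
                       seed = 1L) {
  frequency_law <- match.arg(frequency_law)
  cfg <- list(
    n_true_clones = check_scalar_int(n_true_clones, 1L, "n_true_clones"),
    frequency_law = frequency_law,
    power_exponent = power_exponent,
    freq_cap = freq_cap,
    lognormal_sigma = lognormal_sigma,
    ir_depth = check_scalar_int(ir_depth, 0L, "ir_depth"),
    rna_depth = check_scalar_int(rna_depth, 0L, "rna_depth"),
    error_rate = error_rate,
    quality_true = unname(quality_true),
    quality_artifact = unname(quality_artifact),
    read_noise_sd = read_noise_sd,
    n_quality_features = check_scalar_int(n_quality_features, 1L,
                                          "n_quality_features"),
    v_gene_table = v_gene_table,
    d_gene_table = d_gene_table,
    j_gene_table = j_gene_table,
    cdr3_lengths = as.integer(cdr3_lengths),
    cdr3_length_weights = cdr3_length_weights,
    shared_clone_fraction = shared_clone_fraction,
    seed = check_scalar_int(seed, -.Machine$integer.max, "seed")
  )
  if (!is.numeric(cfg$power_exponent) || cfg$power_exponent <= 1) {
    abort("`power_exponent` must exceed 1.", class = "repfilter_argument_error")
  }
  if (!is.numeric(cfg$freq_cap) || cfg$freq_cap <= 1) {
    abort("`freq_cap` must exceed 1.", class = "repfilter_argument_error")
  }
  if (!is.numeric(cfg$lognormal_sigma) || cfg$lognormal_sigma <= 0) {
    abort("`lognormal_sigma` must be positive.",
          class = "repfilter_argument_error")
  }
  if (!is.numeric(cfg$error_rate) || cfg$error_rate < 0 || cfg$error_rate >= 1) {
    abort("`error_rate` must lie in [0, 1).",
          class = "repfilter_argument_error")
  }
  for (nm in c("quality_true", "quality_artifact")) {
    q <- cfg[[nm]]
    if (length(q) != 2L || !is.numeric(q) || q[2L] <= 0) {
      abort(sprintf("`%s` must be c(mean, sd) with sd > 0.", nm),
            class = "repfilter_argument_error")
    }
  }
  if (!is.numeric(cfg$read_noise_sd) || cfg$read_noise_sd < 0) {
    abort("`read_noise_sd` must be non-negative.",
          class = "repfilter_argument_error")
  }
  if (cfg$n_quality_features > 4L) {
    abort("`n_quality_features` must be 1-4 (mean, min, max, sd).",
          class = "repfilter_argument_error")
  }
  for (nm in c("v_gene_table", "d_gene_table", "j_gene_table")) {
    tab <- cfg[[nm]]
    if (!length(tab) || is.null(names(tab)) || any(tab < 0) || sum(tab) <= 0) {
      abort(sprintf("`%s` must be a named non-negative weight vector.", nm),
            class = "repfilter_argument_error")
    }
    cfg[[nm]] <- tab / sum(tab)
  }
  if (length(cfg$cdr3_lengths) != length(cfg$cdr3_length_weights) ||
      any(cfg$cdr3_lengths < 3L)) {
    abort("CDR3 length law needs matching lengths (>= 3) and weights.",
          class = "repfilter_argument_error")
  }
  if (cfg$shared_clone_fraction < 0 || cfg$shared_clone_fraction > 1) {
    abort("`shared_clone_fraction` must lie in [0, 1].",
          class = "repfilter_argument_error")
  }
  structure(cfg, class = "sim_config")
}

# n unique random CDR3 amino-acid strings: "C" + random core + "F".
gen_cdr3 <- function(n, lengths, weights, existing = character()) {
  draw <- function(m) {
    L <- sample(length(lengths), m, replace = TRUE, prob = weights)
    core_len <- lengths[L] - 2L
    maxc <- max(core_len)
    mat <- matrix("", m, maxc)
    for (j in seq_len(maxc)) {
      hit <- core_len >= j
      mat[hit, j] <- sample(aa_alphabet, sum(hit), replace = TRUE)
    }
    paste0("C", do.call(paste0, asplit(mat, 2L)), "F")
  }
  out <- draw(n)
  for (i in 1:100) {
    bad <- duplicated(out) | out %in% existing
    if (!any(bad)) {
      return(out)
    }
    out[bad] <- draw(sum(bad))
  }
  abort("Could not generate enough unique CDR3 sequences.",
        class = "repfilter_degenerate_error")
}

# Substitute one random residue of each sequence for a random amino acid.
substitute_residue <- function(seqs) {
  L <- nchar(seqs)
  pos <- 1L + floor(runif(length(seqs)) * L)
  substr(seqs, pos, pos) <- sample(aa_alphabet, length(seqs), replace = TRUE)
  seqs
}

# One novel CDR3 per artifact read, each a (possibly repeated) point
# substitution of its source clone's CDR3. Candidates colliding with an
# existing key or with each other are re-drawn; persistent collisions (the
# single-substitution neighbourhood of a short, highly expressed CDR3 is
# small) escalate by mutating the already-mutated candidate again.
mutate_cdr3 <- function(src, existing) {
  cand <- substitute_residue(src)
  for (i in 1:100) {
    bad <- duplicated(cand) | cand %in% existing
    if (!any(bad)) {
      return(cand)
    }
    cand[bad] <- substitute_residue(cand[bad])
  }
  abort("Could not generate unique artifact CDR3 sequences.",
        class = "repfilter_degenerate_error")
}

clone_sizes <- function(config, n) {
  switch(config$frequency_law,
    power_law = {
      a <- config$power_exponent
      u <- runif(n)
      # inverse CDF of the Pareto density ~ x^(-a) truncated to [1, freq_cap]
      (1 - u * (1 - config$freq_cap^(1 - a)))^(1 / (1 - a))
    },
    log_normal = rlnorm(n, 0, config$lognormal_sigma)
  )
}

#' Generate a latent true repertoire
#'
#' Draws `n_true_clones` clones with unique CDR3 amino-acid sequences,
#' V/D/J gene calls from the configured gene tables and normalised clone
#' frequencies from the configured frequency law. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble `clone_id`, `cdr3_aa`, `v_gene`, `d_gene`, `j_gene`,
#'   `frequency` (summing to 1).
#' @export
simulate_repertoire <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, repertoire_draw(config))
}

repertoire_draw <- function(config, n = config$n_true_clones,
                            cdr3 = NULL) {
  sizes <- clone_sizes(config, n)
  if (is.null(cdr3)) {
    cdr3 <- gen_cdr3(n, config$cdr3_lengths, config$cdr3_length_weights)
  }
  tibble(
    clone_id = seq_len(n),
    cdr3_aa = cdr3,
    v_gene = sample(names(config$v_gene_table), n, replace = TRUE,
                    prob = config$v_gene_table),
    d_gene = sample(names(config$d_gene_table), n, replace = TRUE,
                    prob = config$d_gene_table),
    j_gene = sample(names(config$j_gene_table), n, replace = TRUE,
                    prob = config$j_gene_table),
    frequency = sizes / sum(sizes)
  )
}

#' Sequence a repertoire into a clonotype table
#'
#' Draws `depth` reads from the clone-frequency multinomial; each read
#' independently becomes an artifact with probability `error_rate`,
#' spawning a novel singleton clonotype whose CDR3 is a point-mutated copy
#' of its source clone's. Per-clonotype quality features summarise the
#' clonotype's per-read quality draws (mean/min/max/sd; the sd of a single
#' read is 0); true and artifact clonotypes draw their clonotype-level
#' quality from the configured true and degraded distributions.
#'
#' @param repertoire A latent repertoire from [simulate_repertoire()].
#' @param config The [sim_config()] used to generate it.
#' @param platform `"IR"` or `"RNA"` (sets the default depth).
#' @param depth Number of reads; defaults to the platform depth of
#'   `config`.
#' @param seed Seed of this sequencing run (defaults derive from
#'   `config$seed`).
#' @param sample_id Sample identifier stamped on the output.
#' @return A list with `sample` (clonotype tibble) and `truth` (tibble
#'   `clonotype_key`, `is_artifact`, `true_frequency`, `source_clone`,
#'   `observed`; true frequencies sum to 1 over non-artifact rows).
#' @export
simulate_sample <- function(repertoire, config = sim_config(),
                            platform = c("IR", "RNA"), depth = NULL,
                            seed = NULL, sample_id = "S1") {
  stopifnot(inherits(config, "sim_config"))
  platform <- match.arg(platform)
  if (is.null(depth)) {
    depth <- if (platform == "IR") config$ir_depth else config$rna_depth
  }
  depth <- check_scalar_int(depth, 0L, "depth")
  if (is.null(seed)) {
    seed <- config$seed + if (platform == "IR") 1L else 2L
  }
  withr::with_seed(seed,
    sequence_draw(repertoire, config, platform, depth, sample_id))
}

sequence_draw <- function(repertoire, config, platform, depth, sample_id) {
  k_feat <- config$n_quality_features
  feat <- quality_feature_names[seq_len(k_feat)]
  n <- nrow(repertoire)
  truth_true <- tibble(
    clonotype_key = repertoire$cdr3_aa,
    is_artifact = FALSE,
    true_frequency = repertoire$frequency,
    source_clone = repertoire$clone_id,
    observed = FALSE
  )
  empty <- {
    s <- tibble(sample_id = character(), platform = character(),
                cdr3_aa = character(), v_gene = character(),
                d_gene = character(), j_gene = character(),
                read_count = integer())
    for (f in feat) s[[f]] <- double()
    s
  }
  if (depth == 0L) {
    return(list(sample = empty, truth = truth_true))
  }

  counts <- drop(rmultinom(1L, depth, repertoire$frequency))
  art_counts <- rbinom(n, counts, config$error_rate)
  true_counts <- counts - art_counts

  # true clonotypes: summaries of per-read quality draws around a
  # clonotype-level mean
  idx <- which(true_counts > 0L)
  qt <- config$quality_true
  mu <- pmax(rnorm(length(idx), qt[1L], qt[2L]), 0)
  nr <- true_counts[idx]
  reads <- pmax(rnorm(sum(nr), rep(mu, nr), config$read_noise_sd), 0)
  dt <- data.table::data.table(id = rep.int(seq_along(idx), nr), q = reads)
  agg <- dt[, list(q_mean = mean(q), q_min = min(q), q_max = max(q),
                   q_sd = sd(q)), by = "id"]
  data.table::setorderv(agg, "id")
  agg$q_sd[is.na(agg$q_sd)] <- 0

  true_tbl <- tibble(
    sample_id = sample_id, platform = platform,
    cdr3_aa = repertoire$cdr3_aa[idx],
    v_gene = repertoire$v_gene[idx],
    d_gene = repertoire$d_gene[idx],
    j_gene = repertoire$j_gene[idx],
    read_count = as.integer(nr)
  )
  for (f in feat) true_tbl[[f]] <- agg[[f]]

  # artifact clonotypes: one novel singleton per artifact read
  m <- sum(art_counts)
  if (m > 0L) {
    src <- rep.int(seq_len(n), art_counts)
    art_cdr3 <- mutate_cdr3(repertoire$cdr3_aa[src], repertoire$cdr3_aa)
    qa <- config$quality_artifact
    art_mu <- pmax(rnorm(m, qa[1L], qa[2L]), 0)
    art_read <- pmax(rnorm(m, art_mu, config$read_noise_sd), 0)
    art_tbl <- tibble(
      sample_id = sample_id, platform = platform,
      cdr3_aa = art_cdr3,
      v_gene = repertoire$v_gene[src],
      d_gene = repertoire$d_gene[src],
      j_gene = repertoire$j_gene[src],
      read_count = 1L
    )
    art_feat <- list(q_mean = art_read, q_min = art_read, q_max = art_read,
                     q_sd = rep(0, m))
    for (f in feat) art_tbl[[f]] <- art_feat[[f]]
    truth_art <- tibble(
      clonotype_key = art_cdr3,
      is_artifact = TRUE,
      true_frequency = 0,
      source_clone = repertoire$clone_id[src],
      observed = TRUE
    )
  } else {
    art_tbl <- empty
    truth_art <- truth_true[0L, ]
  }

  truth_true$observed <- true_counts > 0L
  sample_tbl <- bind_rows(true_tbl, art_tbl)
  list(sample = sample_tbl, truth = bind_rows(truth_true, truth_art))
}

#' Simulate one matched IR-seq/RNA-seq pair
#'
#' Draws one latent repertoire and sequences it on both platforms at the
#' configured depths. Both samples capture the same clone frequencies; they
#' differ in depth and in their platform-specific artifact draws.
#'
#' @inheritParams simulate_sample
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` for this pair.
#' @return A list `sample_id`, `repertoire`, `ir`, `rna`, `truth` (list
#'   with `ir` and `rna` truth tables).
#' @export
simulate_pair <- function(config = sim_config(), sample_id = "S1",
                          seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) {
    config$seed <- check_scalar_int(seed, -.Machine$integer.max, "seed")
  }
  repertoire <- simulate_repertoire(config)
  ir <- simulate_sample(repertoire, config, "IR", seed = config$seed + 1L,
                        sample_id = sample_id)
  rna <- simulate_sample(repertoire, config, "RNA", seed = config$seed + 2L,
                         sample_id = sample_id)
  list(sample_id = sample_id, repertoire = repertoire,
       ir = ir$sample, rna = rna$sample,
       truth = list(ir = ir$truth, rna = rna$truth))
}

#' Simulate a cohort of matched pairs
#'
#' Generates `n_samples` matched pairs. Repertoires are independent across
#' samples except for an optional shared clone pool
#' (`shared_clone_fraction` of each repertoire's clones share their CDR3
#' and gene calls across all samples, with per-sample frequencies), which
#' makes cross-sample clonotype sharing testable against known pool
#' membership. All seeds derive from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of pairs (>= 1).
#' @return A list of pairs as returned by [simulate_pair()], with an
#'   attribute `pool` holding the shared-pool CDR3 keys (possibly empty).
#' @export
simulate_cohort <- function(config = sim_config(), n_samples = 5L) {
  stopifnot(inherits(config, "sim_config"))
  n_samples <- check_scalar_int(n_samples, 1L, "n_samples")
  n_pool <- round(config$shared_clone_fraction * config$n_true_clones)
  pool <- if (n_pool > 0L) {
    withr::with_seed(config$seed, tibble(
      cdr3_aa = gen_cdr3(n_pool, config$cdr3_lengths,
                         config$cdr3_length_weights),
      v_gene = sample(names(config$v_gene_table), n_pool, replace = TRUE,
                      prob = config$v_gene_table),
      d_gene = sample(names(config$d_gene_table), n_pool, replace = TRUE,
                      prob = config$d_gene_table),
      j_gene = sample(names(config$j_gene_table), n_pool, replace = TRUE,
                      prob = config$j_gene_table)
    ))
  } else {
    NULL
  }
  pairs <- purrr::map(seq_len(n_samples), function(s) {
    sid <- sprintf("S%02d", s)
    cfg <- config
    cfg$seed <- config$seed + 1000L * s
    repertoire <- withr::with_seed(cfg$seed, {
      rep_all <- repertoire_draw(cfg)
      if (n_pool > 0L) {
        # overwrite the identities (not frequencies) of the first clones
        # with the shared pool, re-drawing private CDR3s that collide
        priv <- rep_all$cdr3_aa[-seq_len(n_pool)]
        clash <- priv %in% pool$cdr3_aa
        if (any(clash)) {
          priv[clash] <- gen_cdr3(sum(clash), cfg$cdr3_lengths,
                                  cfg$cdr3_length_weights,
                                  existing = c(pool$cdr3_aa, priv))
        }
        rep_all$cdr3_aa <- c(pool$cdr3_aa, priv)
        rep_all$v_gene[seq_len(n_pool)] <- pool$v_gene
        rep_all$d_gene[seq_len(n_pool)] <- pool$d_gene
        rep_all$j_gene[seq_len(n_pool)] <- pool$j_gene
      }
      rep_all
    })
    ir <- simulate_sample(repertoire, cfg, "IR", seed = cfg$seed + 1L,
                          sample_id = sid)
    rna <- simulate_sample(repertoire, cfg, "RNA", seed = cfg$seed + 2L,
                           sample_id = sid)
    list(sample_id = sid, repertoire = repertoire,
         ir = ir$sample, rna = rna$sample,
         truth = list(ir = ir$truth, rna = rna$truth))
  })
  attr(pairs, "pool") <- if (is.null(pool)) character() else pool$cdr3_aa
  pairs
}
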