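#' Generate the gene universe and its ground truth
#'
#' Draws a universe of gene symbols with baseline log2 means for reference
#' sample A uniform over `base_mean_range`, designates `n_deg` genes as truly
#' differential, and samples their log2 effects (B minus A).  Effect
#' magnitudes are `effect_size * (0.6 + Exp(mean 0.4))` with random sign, so
#' the mean absolute effect equals `effect_size` while no true DEG falls
#' below `0.6 * effect_size`; non-DEG genes have true effect exactly 0.
#' Natural-scale profiles for A and B are `2^` the log2 means, hence
#' strictly positive.
#'
#' @param config a [sim_config()].
#' @return a list with elements `genes`, `profile_a`, `profile_b`
#'   (natural-scale named vectors), `base_log2_a`, `noise_sd_gene` (per-gene
#'   replicate noise sd implied by the intensity-dependent noise model), and
#'   `truth` (data frame: gene, true_effect, is_deg).
#' @export
generate_universe <- function(config) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  set.seed(derive_seed(config$seed, 1L))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  base_a <- runif(config$n_genes, config$base_mean_range[1],
                  config$base_mean_range[2])
  effect <- numeric(config$n_genes)
  deg_idx <- integer(0)
  if (config$n_deg > 0) {
    deg_idx <- sort(sample.int(config$n_genes, config$n_deg))
    magnitude <- config$effect_size * (0.6 + rexp(config$n_deg, rate = 2.5))
    sign_ <- sample(c(-1, 1), config$n_deg, replace = TRUE)
    effect[deg_idx] <- sign_ * magnitude
  }
  log2_a <- base_a
  log2_b <- base_a + effect
  intensity <- (log2_a + log2_b) / 2
  noise_sd_gene <- config$noise_sd +
    config$intensity_noise_slope * (max(intensity) - intensity)
  truth <- data.frame(gene = genes, true_effect = effect,
                      is_deg = seq_along(genes) %in% deg_idx,
                      stringsAsFactors = FALSE)
  list(genes = genes,
       profile_a = setNames(2^log2_a, genes),
       profile_b = setNames(2^log2_b, genes),
       base_log2_a = setNames(log2_a, genes),
       noise_sd_gene = setNames(noise_sd_gene, genes),
       truth = truth)
}

#' Mix two natural-scale profiles
#'
#' Titration samples are built on the natural intensity scale:
#' `fraction_a * A + (1 - fraction_a) * B` elementwise.  Sample C uses
#' `fraction_a = 0.75` and sample D `fraction_a = 0.25`; any log2 transform
#' is applied only afterwards by the expression generator.
#'
#' @param profile_a,profile_b nonnegative natural-scale vectors of equal
#'   length.
#' @param fraction_a mixing proportion of A, in \[0, 1\].
#' @return the mixture profile.
#' @export
mix_samples <- function(profile_a, profile_b, fraction_a) {
  if (length(profile_a) != length(profile_b))
    stop_input("profiles must have equal length")
  if (any(profile_a < 0) || any(profile_b < 0))
    stop_input("natural-scale profiles must be nonnegative")
  assert_scalar_number(fraction_a, "fraction_a", min = 0, max = 1)
  fraction_a * profile_a + (1 - fraction_a) * profile_b
}

type_mixing_fractions <- c(A = 1, B = 0, C = 0.75, D = 0.25)

# Realize a platform's probe content from the universe: gene dropout,
# multi-probe genes, and (GEH-like) duplicated probe IDs.  Returns one row
# per physical probe; `probe_id` may repeat when duplicate IDs are injected.
realize_platform <- function(platform, genes, seed) {
  set.seed(seed)
  n <- length(genes)
  keep_n <- max(1L, round((1 - platform$dropout_rate) * n))
  kept <- sort(sample.int(n, keep_n))
  kept_genes <- genes[kept]
  n_multi <- round(platform$multi_probe_rate * keep_n)
  multi <- if (n_multi > 0) sample.int(keep_n, n_multi) else integer(0)
  n_probes_per_gene <- rep(1L, keep_n)
  if (n_multi > 0)
    n_probes_per_gene[multi] <- sample(2:3, n_multi, replace = TRUE)
  gene_of_probe <- rep(kept_genes, n_probes_per_gene)
  probe_id <- sprintf("%s_%06d", platform$name, seq_along(gene_of_probe))
  n_dup <- round(platform$duplicate_id_rate * length(probe_id))
  rows <- data.frame(probe_id = probe_id, gene = gene_of_probe,
                     stringsAsFactors = FALSE)
  if (n_dup > 0) {
    dup_rows <- rows[sample.int(nrow(rows), n_dup), , drop = FALSE]
    rows <- rbind(rows, dup_rows)
    rows <- rows[order(match(rows$probe_id, probe_id)), , drop = FALSE]
  }
  rownames(rows) <- NULL
  rows
}

#' Generate replicated expression matrices per platform and site
#'
#' For each platform the probe content is realized from the universe with
#' the descriptor's dropout, multi-probe and duplicate-ID rates; for each
#' test site a probes-by-(4 types x n_reps) matrix of log2 signals is drawn.
#' Signals are the log2 of the natural-scale type mean (A, B, and the 3:1 /
#' 1:3 mixtures C, D), plus an additive per-probe site offset
#' (sd `site_sd`), plus replicate noise whose sd is
#' `noise_sd + intensity_noise_slope * (max_mean - gene mean)` so that
#' low-intensity genes are noisier.
#'
#' @param config a [sim_config()].
#' @param universe output of [generate_universe()].
#' @return a list with `matrices` (nested: platform then `site1..siteK`,
#'   each an `ExpressionMatrix` on the log2 scale) and `annotations` (per
#'   platform, a data frame probe_id/gene with one row per unique probe ID).
#' @export
generate_expression <- function(config, universe) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  type_log2 <- vapply(type_mixing_fractions, function(f) {
    log2(mix_samples(universe$profile_a, universe$profile_b, f))
  }, numeric(length(universe$genes)))  # genes x 4 types
  rownames(type_log2) <- universe$genes
  matrices <- list()
  annotations <- list()
  for (p in seq_along(config$platforms)) {
    platform <- config$platforms[[p]]
    rows <- realize_platform(platform, universe$genes,
                             derive_seed(config$seed, 1000L * p))
    ann <- unique(rows)
    annotations[[platform$name]] <- ann
    gene_idx <- match(rows$gene, universe$genes)
    sd_row <- universe$noise_sd_gene[gene_idx]
    per_site <- list()
    for (s in seq_len(config$n_sites)) {
      set.seed(derive_seed(config$seed, 1000L * p + s))
      site_offset <- rnorm(nrow(rows), sd = config$site_sd)
      n_col <- 4L * config$n_reps
      types <- rep(names(type_mixing_fractions), each = config$n_reps)
      vals <- matrix(0, nrow(rows), n_col)
      for (j in seq_len(n_col)) {
        mu <- type_log2[gene_idx, types[j]] + site_offset
        vals[, j] <- mu + rnorm(nrow(rows), sd = sd_row)
      }
      sample_ids <- sprintf("%s_s%d_%s_r%d", platform$name, s, types,
                            rep(seq_len(config$n_reps), times = 4L))
      colnames(vals) <- sample_ids
      meta <- data.frame(sample_id = sample_ids, type = types,
                         site = sprintf("site%d", s),
                         platform = platform$name, stringsAsFactors = FALSE)
      per_site[[sprintf("site%d", s)]] <-
        expression_matrix(vals, rows$probe_id, meta, scale = "log2")
    }
    matrices[[platform$name]] <- per_site
  }
  list(matrices = matrices, annotations = annotations)
}

#' Generate an RT-PCR-like reference table
#'
#' A low-noise assay on a gene subset: `rtpcr_n_genes` genes measured
#' directly (no probes), `rtpcr_n_reps` replicates per sample type, with
#' Gaussian log2 noise of sd `rtpcr_noise_sd` (never above the microarray
#' noise).  The subset includes `rtpcr_deg_fraction` true DEGs (capped by
#' availability); remaining slots are filled with non-DEG genes.
#'
#' @param config a [sim_config()].
#' @param universe output of [generate_universe()].
#' @return an `ExpressionMatrix` whose rows are gene symbols, platform
#'   `"RTPCR"`.
#' @export
generate_rtpcr <- function(config, universe) {
  if (!inherits(config, "sim_config")) stop_config("config must be a sim_config")
  if (config$rtpcr_n_genes > length(universe$genes))
    stop_config("rtpcr_n_genes exceeds the universe size")
  set.seed(derive_seed(config$seed, 777L))
  truth <- universe$truth
  deg_pool <- truth$gene[truth$is_deg]
  non_pool <- truth$gene[!truth$is_deg]
  n_deg_assay <- min(round(config$rtpcr_deg_fraction * config$rtpcr_n_genes),
                     length(deg_pool))
  n_non_assay <- min(config$rtpcr_n_genes - n_deg_assay, length(non_pool))
  assayed <- sort(c(sample(deg_pool, n_deg_assay),
                    sample(non_pool, n_non_assay)))
  type_log2 <- vapply(type_mixing_fractions, function(f) {
    log2(mix_samples(universe$profile_a[assayed], universe$profile_b[assayed], f))
  }, numeric(length(assayed)))
  n_col <- 4L * config$rtpcr_n_reps
  types <- rep(names(type_mixing_fractions), each = config$rtpcr_n_reps)
  vals <- matrix(0, length(assayed), n_col)
  for (j in seq_len(n_col)) {
    vals[, j] <- type_log2[, types[j]] +
      rnorm(length(assayed), sd = config$rtpcr_noise_sd)
  }
  sample_ids <- sprintf("RTPCR_%s_r%d", types,
                        rep(seq_len(config$rtpcr_n_reps), times = 4L))
  colnames(vals) <- sample_ids
  meta <- data.frame(sample_id = sample_ids, type = types, site = "RTPCR",
                     platform = "RTPCR", stringsAsFactors = FALSE)
  expression_matrix(vals, assayed, meta, scale = "log2")
}

#' Generate a synthetic gene-set collection
#'
#' Draws `n_sets` sets of symbols from the universe with sizes uniform in
#' `size_range`.  A configurable fraction of sets is "enriched": half of
#' each such set's slots are filled from the true DEG pool (capped by
#' availability), so enriched sets concentrate at good ranks on
#' strong-signal data.
#'
#' @param universe output of [generate_universe()] (or a character vector of
#'   gene symbols).
#' @param n_sets number of sets.
#' @param size_range inclusive size interval.
#' @param enriched_fraction fraction of sets over-sampling DEG genes.
#' @param truth data frame with columns gene/is_deg; required when
#'   `enriched_fraction > 0`.
#' @param seed RNG seed.
#' @return a named list of character vectors with a logical attribute
#'   `enriched`.
#' @export
generate_gene_sets <- function(universe, n_sets = 186L,
                               size_range = c(10L, 60L),
                               enriched_fraction = 0, truth = NULL,
                               seed = 1L) {
  genes <- if (is.list(universe)) universe$genes else as.character(universe)
  if (is.null(truth) && is.list(universe)) truth <- universe$truth
  n_sets <- assert_count(n_sets, "n_sets", min = 1)
  if (size_range[2] > length(genes))
    stop_config("set_size_range upper bound exceeds the universe size")
  if (enriched_fraction > 0 && is.null(truth))
    stop_config("truth is required when enriched_fraction > 0")
  set.seed(seed)
  sizes <- sample(seq.int(size_range[1], size_range[2]), n_sets, replace = TRUE)
  n_enriched <- round(enriched_fraction * n_sets)
  enriched <- seq_len(n_sets) %in%
    (if (n_enriched > 0) sample.int(n_sets, n_enriched) else integer(0))
  deg_pool <- if (!is.null(truth)) truth$gene[truth$is_deg] else character(0)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (enriched[i] && length(deg_pool)) {
      n_from_deg <- min(ceiling(sizes[i] / 2), length(deg_pool))
      members_deg <- sample(deg_pool, n_from_deg)
      members_rest <- sample(setdiff(genes, members_deg),
                             sizes[i] - n_from_deg)
      sets[[i]] <- sort(c(members_deg, members_rest))
    } else {
      sets[[i]] <- sort(sample(genes, sizes[i]))
    }
  }
  names(sets) <- sprintf("SET_%04d", seq_len(n_sets))
  attr(sets, "enriched") <- setNames(enriched, names(sets))
  sets
}

#' Simulate a complete benchmark dataset
#'
#' Runs the whole generator: universe and ground truth, per-platform/site
#' expression matrices with annotations, the RT-PCR-like reference table,
#' and the gene-set collection.  With `outdir` set, all artifacts are also
#' written as plain-text files (expression and metadata TSV per platform and
#' site, annotation TSV per platform, RT-PCR TSV, truth TSV, GMT).
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return a list: `config`, `universe`, `truth`, `expression`,
#'   `annotations`, `rtpcr`, `gene_sets`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  universe <- generate_universe(config)
  expr <- generate_expression(config, universe)
  rtpcr <- generate_rtpcr(config, universe)
  sets <- generate_gene_sets(universe, n_sets = config$n_sets,
                             size_range = config$set_size_range,
                             enriched_fraction = config$enriched_fraction,
                             truth = universe$truth,
                             seed = derive_seed(config$seed, 555L))
  bundle <- list(config = config, universe = universe,
                 truth = universe$truth, expression = expr$matrices,
                 annotations = expr$annotations, rtpcr = rtpcr,
                 gene_sets = sets)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (pn in names(expr$matrices)) {
      for (sn in names(expr$matrices[[pn]])) {
        base <- file.path(outdir, sprintf("expression_%s_%s", pn, sn))
        write_expression_tsv(expr$matrices[[pn]][[sn]],
                             paste0(base, ".tsv"),
                             paste0(base, "_metadata.tsv"))
      }
      write.table(expr$annotations[[pn]],
                  file.path(outdir, sprintf("annotation_%s.tsv", pn)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_expression_tsv(rtpcr, file.path(outdir, "rtpcr.tsv"),
                         file.path(outdir, "rtpcr_metadata.tsv"))
    write.table(universe$truth, file.path(outdir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
  }
  bundle
}
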