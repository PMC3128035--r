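method_display <- c(wad = "WAD", ad = "AD", fc = "FC", rp = "RP",
                    modt = "modT", samt = "samT", shrt = "shrT",
                    ibmt = "ibmT")

comparison_classes <- list(AB = c("A", "B"), CD = c("C", "D"))

default_x_grid <- function(m) {
  grid <- c(seq(10L, 100L, by = 10L), 200L, 500L, 1000L, 2000L, 5000L)
  unique(grid[grid <= m])
}

preprocess_platform <- function(mats, floor = 0.169) {
  lapply(mats, function(em) {
    if (anyDuplicated(em$probe_ids)) {
      em <- to_natural_scale(em)
      em <- average_duplicate_probes(em)
      em <- floor_values(em, floor = floor, quiet = TRUE)
      em <- log2_transform(em)
    }
    em
  })
}

#' Run the full benchmarking pipeline
#'
#' Orchestrates the complete study design on synthetic data: simulate,
#' preprocess (duplicate-probe averaging, floor, log2 where the platform
#' requires it), rank with all eight methods for the "A versus B" and
#' "C versus D" comparisons at every site of every platform, define truth
#' sets from the RT-PCR-like table (FDR < alpha and |AD| > cutoff), and
#' evaluate: per-site and site-averaged AUCs, POG-versus-X curves among
#' sites, Spearman matrices with average-linkage merge trees, gene-set
#' enrichment scores with set-level intra- and inter-platform POG curves,
#' and intersection-union ratios of the realized gene sets.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, result tables are written
#'   as TSV, merge trees as newick text, and a JSON run manifest is
#'   emitted.
#' @param fdr_alpha FDR threshold for the truth rule (strict `<`).
#' @param ad_cutoff absolute-AD threshold for the truth rule (strict `>`).
#' @param x_grid top-X grid for gene-level POG curves (defaults to
#'   10,20,...,100 then log-spaced).
#' @param set_x_grid top-X grid for set-level POG curves.
#' @param floor floor intensity used when preprocessing duplicate-ID
#'   platforms.
#' @return a result bundle (list); see Details in the package vignette.
#' @export
run_full <- function(config, outdir = NULL, fdr_alpha = 0.05, ad_cutoff = 1,
                     x_grid = NULL, set_x_grid = NULL, floor = 0.169) {
  sim <- simulate_dataset(config, outdir = if (is.null(outdir)) NULL
                          else file.path(outdir, "data"))
  matrices <- lapply(sim$expression, preprocess_platform, floor = floor)

  # truth sets from the RT-PCR-like reference
  truths <- list()
  for (comp in names(comparison_classes)) {
    cls <- comparison_classes[[comp]]
    des <- class_design(sim$rtpcr, cls[1], cls[2], min_reps = 2L)
    for (metric in c("fdr", "ad")) {
      thr <- if (metric == "fdr") fdr_alpha else ad_cutoff
      truths[[sprintf("%s_%s", comp, toupper(metric))]] <-
        define_truth(sim$rtpcr, des, metric = metric, threshold = thr)
    }
  }

  # ranked lists, probe level (for AUC/POG/Spearman) and gene level (E_G)
  ranked <- list(); ranked_gene <- list(); labels <- character(0)
  auc_rows <- list()
  for (pn in names(matrices)) {
    ann <- sim$annotations[[pn]]
    ranked[[pn]] <- list(); ranked_gene[[pn]] <- list()
    for (sn in names(matrices[[pn]])) {
      em <- matrices[[pn]][[sn]]
      em_gene <- collapse_probes_to_genes(em, ann)
      site_num <- sub("site", "", sn)
      for (comp in names(comparison_classes)) {
        cls <- comparison_classes[[comp]]
        des <- class_design(em, cls[1], cls[2], min_reps = 2L)
        des_gene <- class_design(em_gene, cls[1], cls[2], min_reps = 2L)
        for (mth in ranking_methods()) {
          lab <- sprintf("%s_%s_%s", method_display[[mth]], comp, site_num)
          scores <- ranking_statistic(mth, em, des)
          ranked[[pn]][[lab]] <- rank_genes(scores, ties = "average")
          gscores <- ranking_statistic(mth, em_gene, des_gene)
          ranked_gene[[pn]][[lab]] <- rank_genes(gscores, ties = "average")
          labels <- c(labels, sprintf("%s_%s", pn, lab))
          for (tn in grep(paste0("^", comp), names(truths), value = TRUE)) {
            auc_rows[[length(auc_rows) + 1L]] <- data.frame(
              platform = pn, method = method_display[[mth]],
              comparison = comp, metric = sub("^[A-Z]+_", "", tn),
              site = site_num,
              auc = 100 * auc(ranked[[pn]][[lab]], truths[[tn]], map = ann),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  auc_table <- do.call(rbind, auc_rows)
  auc_avg <- stats::aggregate(auc ~ platform + method + comparison + metric,
                              data = auc_table, FUN = mean)

  # POG among sites, per platform / method / comparison
  n_sites <- config$n_sites
  pog_rows <- list()
  for (pn in names(ranked)) {
    m_universe <- nrow(ranked[[pn]][[1L]])
    grid <- x_grid %||% default_x_grid(m_universe)
    for (comp in names(comparison_classes)) {
      for (mth in ranking_methods()) {
        lists <- lapply(seq_len(n_sites), function(s)
          ranked[[pn]][[sprintf("%s_%s_%d", method_display[[mth]], comp, s)]])
        for (X in grid) {
          pog_rows[[length(pog_rows) + 1L]] <- data.frame(
            platform = pn, method = method_display[[mth]], comparison = comp,
            X = X, pog = pog(lists, X), stringsAsFactors = FALSE)
        }
      }
    }
  }
  pog_table <- do.call(rbind, pog_rows)

  clusters <- lapply(ranked, cluster_lists)

  # set-level enrichment, intra- and inter-platform reproducibility
  set_ranked <- list(); etables <- list()
  for (pn in names(ranked_gene)) {
    set_ranked[[pn]] <- list(); etables[[pn]] <- list()
    for (lab in names(ranked_gene[[pn]])) {
      et <- score_gene_sets(ranked_gene[[pn]][[lab]], sim$gene_sets,
                            label = lab)
      etables[[pn]][[lab]] <- et
      set_ranked[[pn]][[lab]] <- rank_gene_sets(et)
    }
  }
  n_scoreable <- min(vapply(etables, function(pl) min(vapply(pl, nrow,
    integer(1))), integer(1)))
  sgrid <- set_x_grid %||%
    unique(pmin(c(5L, 10L, 20L, 50L, 100L, 150L, n_scoreable), n_scoreable))
  set_pog_rows <- list(); iplat_rows <- list()
  platforms <- names(set_ranked)
  for (comp in names(comparison_classes)) {
    for (mth in ranking_methods()) {
      for (pn in platforms) {
        lists <- lapply(seq_len(n_sites), function(s)
          set_ranked[[pn]][[sprintf("%s_%s_%d", method_display[[mth]], comp, s)]])
        universe_ok <- length(unique(vapply(lists, nrow, integer(1)))) == 1L
        for (X in sgrid) {
          set_pog_rows[[length(set_pog_rows) + 1L]] <- data.frame(
            platform = pn, method = method_display[[mth]], comparison = comp,
            X = X,
            pog = if (universe_ok) tryCatch(pog(lists, X),
                                            error = function(e) NA_real_)
                  else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
      if (length(platforms) >= 2L) {
        for (s in seq_len(n_sites)) {
          lists <- lapply(platforms, function(pn)
            set_ranked[[pn]][[sprintf("%s_%s_%d", method_display[[mth]], comp, s)]])
          common <- Reduce(intersect, lapply(lists, `[[`, "probe_id"))
          lists <- lapply(lists, function(l) {
            l <- l[l$probe_id %in% common, , drop = FALSE]
            l$rank <- rank(l$statistic, ties.method = "average")
            l
          })
          for (X in sgrid[sgrid <= length(common)]) {
            iplat_rows[[length(iplat_rows) + 1L]] <- data.frame(
              method = method_display[[mth]], comparison = comp, site = s,
              X = X, pog = pog(lists, X), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  set_pog_table <- do.call(rbind, set_pog_rows)
  interplatform_set_pog <- if (length(iplat_rows))
    do.call(rbind, iplat_rows) else NULL

  # intersection-union ratios of realized set memberships across platforms
  iu_table <- NULL
  if (length(platforms) >= 2L) {
    measured <- lapply(platforms, function(pn) {
      unique(clean_probe_gene_map(sim$annotations[[pn]])$gene)
    })
    ratios <- vapply(sim$gene_sets, function(set) {
      mem <- lapply(measured, function(g) intersect(set, g))
      if (!length(Reduce(union, mem))) NA_real_ else iu_ratio(mem)
    }, numeric(1))
    iu_table <- data.frame(set = names(sim$gene_sets), iu = ratios,
                           row.names = NULL, stringsAsFactors = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("degrank")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "platforms")],
    platforms = lapply(config$platforms, unclass),
    n_lists = length(labels),
    labels = labels)

  bundle <- list(config = config, truth = sim$truth,
                 annotations = sim$annotations, gene_sets = sim$gene_sets,
                 truth_sets = truths, ranked = ranked,
                 ranked_gene = ranked_gene, auc_table = auc_table,
                 auc_avg = auc_avg, pog_table = pog_table,
                 clusters = clusters, enrichment = etables,
                 set_ranked = set_ranked, set_pog_table = set_pog_table,
                 interplatform_set_pog = interplatform_set_pog,
                 iu_table = iu_table, manifest = manifest)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) write.table(df, file.path(outdir, name),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  wt(bundle$auc_table, "auc_per_site.tsv")
  wt(bundle$auc_avg, "auc_average.tsv")
  wt(bundle$pog_table, "pog_gene_level.tsv")
  wt(bundle$set_pog_table, "pog_set_level.tsv")
  if (!is.null(bundle$interplatform_set_pog))
    wt(bundle$interplatform_set_pog, "pog_set_interplatform.tsv")
  if (!is.null(bundle$iu_table)) wt(bundle$iu_table, "iu_ratios.tsv")
  for (pn in names(bundle$clusters)) {
    writeLines(bundle$clusters[[pn]]$newick,
               file.path(outdir, sprintf("cluster_%s.nwk", pn)))
    write.table(round(bundle$clusters[[pn]]$distance, 6),
                file.path(outdir, sprintf("distance_%s.tsv", pn)),
                sep = "\t", quote = FALSE)
  }
  manifest <- bundle$manifest
  data_dir <- file.path(outdir, "data")
  if (dir.exists(data_dir)) {
    files <- list.files(data_dir, full.names = TRUE)
    manifest$file_digests <- as.list(tools::md5sum(files))
    names(manifest$file_digests) <- basename(files)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Summarize a result bundle
#'
#' Produces a markdown summary naming the best method (ties: all listed)
#' per platform, comparison and truth metric by site-averaged AUC, and the
#' POG winner per comparison and top-X cutoff.
#'
#' @param bundle result of [run_full()].
#' @return character vector of markdown lines (invisibly printed with
#'   `cat` when `print = TRUE`).
#' @param print print the summary to the console.
#' @export
report <- function(bundle, print = TRUE) {
  if (is.null(bundle$auc_avg) || !nrow(bundle$auc_avg))
    stop_input("empty result bundle: no AUC table present")
  lines <- c("# Benchmark summary", "", "## Best method by average AUC", "")
  aa <- bundle$auc_avg
  cells <- unique(aa[, c("platform", "comparison", "metric")])
  lines <- c(lines, "| platform | comparison | metric | best (avg AUC) |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(cells))) {
    sub <- aa[aa$platform == cells$platform[i] &
                aa$comparison == cells$comparison[i] &
                aa$metric == cells$metric[i], ]
    best <- sub$method[sub$auc == max(sub$auc)]
    lines <- c(lines, sprintf("| %s | %s | %s | %s (%.2f) |",
                              cells$platform[i], cells$comparison[i],
                              cells$metric[i],
                              paste(sort(best), collapse = ", "),
                              max(sub$auc)))
  }
  lines <- c(lines, "", "## POG winners (inter-site, gene level)", "",
             "| platform | comparison | X | best (POG) |", "|---|---|---|---|")
  pt <- bundle$pog_table
  cells <- unique(pt[, c("platform", "comparison", "X")])
  for (i in seq_len(nrow(cells))) {
    sub <- pt[pt$platform == cells$platform[i] &
                pt$comparison == cells$comparison[i] & pt$X == cells$X[i], ]
    best <- sub$method[sub$pog == max(sub$pog)]
    lines <- c(lines, sprintf("| %s | %s | %d | %s (%.0f) |",
                              cells$platform[i], cells$comparison[i],
                              cells$X[i], paste(sort(best), collapse = ", "),
                              max(sub$pog)))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
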