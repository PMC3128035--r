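test_that("generate_universe obeys the configured counts and degenerate cases", {
  cfg <- sim_config(n_genes = 1000, n_deg = 100, seed = 1)
  u <- generate_universe(cfg)
  expect_length(u$genes, 1000)
  expect_equal(sum(u$truth$is_deg), 100)
  expect_equal(sum(u$truth$true_effect != 0), 100)
  expect_true(all(u$truth$true_effect[!u$truth$is_deg] == 0))

  u0 <- generate_universe(sim_config(n_deg = 0, seed = 1))
  expect_equal(sum(u0$truth$is_deg), 0)
  expect_true(all(u0$profile_a == u0$profile_b))
})

test_that("sampled effect magnitudes average to effect_size", {
  cfg <- sim_config(n_genes = 2000, n_deg = 1000, effect_size = 2.0, seed = 42)
  u <- generate_universe(cfg)
  eff <- abs(u$truth$true_effect[u$truth$is_deg])
  se <- sd(eff) / sqrt(length(eff))
  expect_lt(abs(mean(eff) - 2.0), 3 * se)
  # hard lower bound of the magnitude distribution
  expect_true(all(eff > 0.6 * 2.0))
})

test_that("mix_samples implements the stated natural-scale mixture", {
  expect_equal(mix_samples(c(8, 2), c(4, 6), 0.75), c(7, 3))
  a <- c(1, 5, 9)
  expect_identical(mix_samples(a, c(2, 2, 2), 1), a)
  expect_identical(mix_samples(a, a, 0.5), a)
  expect_error(mix_samples(c(-1, 2), c(1, 2), 0.5), class = "degrank_input_error")
  expect_error(mix_samples(c(1, 2), c(1, 2, 3), 0.5), class = "degrank_input_error")
  expect_error(mix_samples(c(1, 2), c(1, 2), 1.5), class = "degrank_config_error")
})

test_that("generate_expression has the forced shape and zero-noise behaviour", {
  cfg <- sim_config(n_genes = 100, n_deg = 10, n_sites = 3, n_reps = 5,
                    noise_sd = 0, intensity_noise_slope = 0,
                    rtpcr_n_genes = 20, rtpcr_noise_sd = 0,
                    set_size_range = c(5, 20), seed = 3)
  u <- generate_universe(cfg)
  ex <- generate_expression(cfg, u)
  for (pn in names(ex$matrices)) {
    expect_length(ex$matrices[[pn]], 3)
    for (em in ex$matrices[[pn]]) {
      expect_equal(ncol(em$values), 20)  # 4 types x 5 reps
      # zero noise: replicate columns within each type identical
      for (tp in c("A", "B", "C", "D")) {
        cols <- em$values[, em$metadata$type == tp, drop = FALSE]
        expect_equal(max(apply(cols, 1, function(r) diff(range(r)))), 0)
      }
    }
  }
})

test_that("mixture conservation holds exactly on zero-noise output", {
  cfg <- sim_config(n_genes = 50, n_deg = 10, noise_sd = 0,
                    intensity_noise_slope = 0, site_sd = 0,
                    rtpcr_n_genes = 20, rtpcr_noise_sd = 0,
                    set_size_range = c(5, 20), seed = 5)
  u <- generate_universe(cfg)
  ex <- generate_expression(cfg, u)
  em <- ex$matrices[[1]][[1]]
  ann <- ex$annotations[[1]]
  nat <- 2^em$values
  a <- rowMeans(nat[, em$metadata$type == "A", drop = FALSE])
  b <- rowMeans(nat[, em$metadata$type == "B", drop = FALSE])
  cc <- rowMeans(nat[, em$metadata$type == "C", drop = FALSE])
  dd <- rowMeans(nat[, em$metadata$type == "D", drop = FALSE])
  expect_equal(cc, 0.75 * a + 0.25 * b, tolerance = 1e-12)
  expect_equal(dd, 0.25 * a + 0.75 * b, tolerance = 1e-12)
})

test_that("generator output is deterministic under a fixed config", {
  cfg <- sim_config(n_genes = 80, n_deg = 8, rtpcr_n_genes = 30,
                    set_size_range = c(5, 20), seed = 11)
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$rtpcr, b2$rtpcr)
  expect_identical(b1$gene_sets, b2$gene_sets)
})

test_that("truth consistency: non-DEG genes have equal A/B expectations", {
  cfg <- sim_config(n_genes = 300, n_deg = 30, noise_sd = 0.3,
                    intensity_noise_slope = 0, site_sd = 0,
                    n_reps = 50, n_sites = 1,
                    platforms = list(platform_spec("P", 0, 0, 0)),
                    rtpcr_n_genes = 50, rtpcr_noise_sd = 0.2,
                    set_size_range = c(5, 50), seed = 9)
  u <- generate_universe(cfg)
  expect_equal(log2(u$profile_a[!u$truth$is_deg]),
               log2(u$profile_b[!u$truth$is_deg]))
  ex <- generate_expression(cfg, u)
  em <- ex$matrices[[1]][[1]]
  ad <- rowMeans(em$values[, em$metadata$type == "B"]) -
    rowMeans(em$values[, em$metadata$type == "A"])
  non <- !u$truth$is_deg[match(ex$annotations[[1]]$gene, u$genes)]
  # with 50 reps the empirical A-B mean over non-DEGs is near zero
  expect_lt(abs(mean(ad[non])), 0.02)
})

test_that("annotations map every probe to exactly one symbol; duplicates only on GEH-like platforms", {
  cfg <- sim_config(n_genes = 200, n_deg = 20, rtpcr_n_genes = 50,
                    set_size_range = c(5, 20), seed = 13)
  u <- generate_universe(cfg)
  ex <- generate_expression(cfg, u)
  for (pn in names(ex$annotations)) {
    ann <- ex$annotations[[pn]]
    expect_false(anyDuplicated(ann$probe_id) > 0)
    expect_true(all(ann$gene %in% u$genes))
  }
  expect_gt(sum(duplicated(ex$matrices[["GEH"]][[1]]$probe_ids)), 0)
  expect_equal(sum(duplicated(ex$matrices[["AFX"]][[1]]$probe_ids)), 0)
})

test_that("generate_rtpcr has the forced shape and zero-noise exactness", {
  cfg <- sim_config(n_genes = 500, n_deg = 50, rtpcr_n_genes = 200,
                    rtpcr_n_reps = 4, rtpcr_noise_sd = 0,
                    set_size_range = c(5, 50), seed = 17)
  u <- generate_universe(cfg)
  rt <- generate_rtpcr(cfg, u)
  expect_equal(dim(rt$values), c(200, 16))
  ad <- rowMeans(rt$values[, rt$metadata$type == "B"]) -
    rowMeans(rt$values[, rt$metadata$type == "A"])
  expect_equal(unname(ad), u$truth$true_effect[match(rt$probe_ids, u$genes)],
               tolerance = 1e-12)
})

test_that("RT-PCR truth recovers >=90% of assayed true DEGs at the stated power point", {
  # Monte-Carlo power check: effect 2.0, rtpcr noise sd 0.25, 4 reps
  hits <- 0; total <- 0
  for (seed in 1:5) {
    cfg <- sim_config(n_genes = 500, n_deg = 50, effect_size = 2.0,
                      rtpcr_n_genes = 100, rtpcr_n_reps = 4,
                      rtpcr_noise_sd = 0.25, rtpcr_deg_fraction = 0.5,
                      set_size_range = c(5, 50), seed = seed)
    u <- generate_universe(cfg)
    rt <- generate_rtpcr(cfg, u)
    des <- class_design(rt, "A", "B", min_reps = 2)
    ts <- define_truth(rt, des, metric = "fdr", threshold = 0.05)
    truly <- u$truth$is_deg[match(rt$probe_ids, u$genes)]
    hits <- hits + sum(ts$is_deg & truly)
    total <- total + sum(truly)
  }
  expect_gte(hits / total, 0.9)
})

test_that("gene-set generation writes GMT and respects the null case", {
  cfg <- sim_config(seed = 21)
  u <- generate_universe(cfg)
  sets <- generate_gene_sets(u, n_sets = 186, size_range = c(10, 60),
                             enriched_fraction = 0.2, seed = 2)
  expect_length(sets, 186)
  sizes <- lengths(sets)
  expect_true(all(sizes >= 10 & sizes <= 60))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back, lapply(sets, identity)[names(sets)])

  null_sets <- generate_gene_sets(u, n_sets = 50, size_range = c(10, 30),
                                  enriched_fraction = 0, seed = 3)
  expect_false(any(attr(null_sets, "enriched")))

  expect_error(generate_gene_sets(u$genes[1:20], n_sets = 5,
                                  size_range = c(10, 30), seed = 1),
               class = "degrank_config_error")
})

test_that("enriched sets score stochastically better than null sets on strong-signal data", {
  cfg <- sim_config(n_genes = 400, n_deg = 80, effect_size = 2,
                    noise_sd = 0.2, n_sites = 1,
                    platforms = list(platform_spec("P", 0, 0, 0)),
                    rtpcr_n_genes = 100, rtpcr_noise_sd = 0.1,
                    n_sets = 60, set_size_range = c(10, 30),
                    enriched_fraction = 0.2, seed = 31)
  b <- simulate_dataset(cfg)
  em <- collapse_probes_to_genes(b$expression[[1]][[1]], b$annotations[[1]])
  des <- class_design(em, "A", "B")
  ranked <- rank_genes(ad_statistic(em, des), ties = "average")
  et <- score_gene_sets(ranked, b$gene_sets)
  enriched <- attr(b$gene_sets, "enriched")[et$set]
  expect_lt(mean(et$e_g[enriched]), mean(et$e_g[!enriched]))
})

test_that("sim_config rejects invalid fields", {
  expect_error(sim_config(n_deg = 2000), class = "degrank_config_error")
  expect_error(sim_config(rtpcr_n_genes = 5000), class = "degrank_config_error")
  expect_error(sim_config(n_reps = 1), class = "degrank_config_error")
  expect_error(sim_config(enriched_fraction = 1.2), class = "degrank_config_error")
  expect_error(sim_config(rtpcr_noise_sd = 0.9, noise_sd = 0.5),
               class = "degrank_config_error")
  expect_error(sim_config(set_size_range = c(10, 5000)),
               class = "degrank_config_error")
  expect_error(platform_spec("X", dropout_rate = -0.1),
               class = "degrank_config_error")
})

test_that("YAML config round-trips through read_sim_config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 120", "n_deg: 12", "seed: 4",
               "rtpcr_n_genes: 40",
               "set_size_range: [5, 20]",
               "platforms:",
               "  - name: AFX", "    dropout_rate: 0.05",
               "  - name: GEH", "    duplicate_id_rate: 0.02"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 120L)
  expect_equal(vapply(cfg$platforms, `[[`, character(1), "name"),
               c("AFX", "GEH"))
  writeLines("bogus_field: 1", path)
  expect_error(read_sim_config(path), class = "degrank_config_error")
})
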