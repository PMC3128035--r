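test_that("moderated t limit cases: d0 = 0 gives ordinary t, d0 = Inf uses the prior only", {
  em <- random_em(m = 60, n1 = 4, n2 = 4, seed = 21)
  des <- class_design(em, "A", "B")
  t0 <- moderated_t(em, des, d0 = 0)
  v <- em$values
  expect_equal(t0$statistic, oracle_t(v, des$idx1, des$idx2), tolerance = 1e-10)

  tinf <- moderated_t(em, des, d0 = Inf)
  s02 <- attr(tinf, "s02")
  diff <- oracle_ad(v, des$idx1, des$idx2)
  expect_equal(tinf$statistic, diff / sqrt(s02 * (1/4 + 1/4)),
               tolerance = 1e-10)
})

test_that("identical gene variances make modT and shrT rank like AD", {
  set.seed(22)
  base <- rnorm(8)
  shift <- rnorm(30)
  vals <- t(vapply(shift, function(s) base + c(0, 0, 0, 0, s, s, s, s),
                   numeric(8)))
  em <- make_em(vals, c(rep("A", 4), rep("B", 4)))
  des <- class_design(em, "A", "B")
  ad_ranks <- rank_genes(ad_statistic(em, des))$rank
  expect_equal(rank_genes(moderated_t(em, des))$rank, ad_ranks)
  shr <- shrinkage_t(em, des)
  expect_equal(attr(shr, "lambda"), 1)
  expect_equal(rank_genes(shr)$rank, ad_ranks)
})

test_that("moderated t agrees with the limma oracle", {
  skip_if_not_installed("limma")
  for (seed in c(31, 32, 33)) {
    em <- random_em(m = 200, n1 = 5, n2 = 5, seed = seed)
    des <- class_design(em, "A", "B")
    mt <- moderated_t(em, des)
    design <- cbind(1, c(rep(0, 5), rep(1, 5)))
    fit <- limma::eBayes(limma::lmFit(em$values, design))
    expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-6)
    expect_equal(attr(mt, "s02"), fit$s2.prior, tolerance = 1e-6)
    expect_equal(mt$statistic, unname(fit$t[, 2]), tolerance = 1e-6)
  }
})

test_that("samT limit cases and fudge-factor selection", {
  em <- random_em(m = 80, n1 = 4, n2 = 4, seed = 23)
  des <- class_design(em, "A", "B")
  v <- em$values
  s_zero <- sam_t(em, des, s0 = 0)
  expect_equal(s_zero$statistic, oracle_t(v, des$idx1, des$idx2),
               tolerance = 1e-10)
  # enormous s0: denominator effectively constant, ranking equals AD
  s_big <- sam_t(em, des, s0 = 1e9)
  expect_equal(rank_genes(s_big)$rank,
               rank_genes(ad_statistic(em, des))$rank)
  # the selected s0 comes from the percentile grid of the se values
  s_auto <- sam_t(em, des)
  se <- sqrt(oracle_t(v, des$idx1, des$idx2)^0 *
               ((oracle_ad(v, des$idx1, des$idx2) /
                   oracle_t(v, des$idx1, des$idx2))^2))
  grid <- quantile(se, seq(0, 1, by = 0.05), names = FALSE)
  expect_true(any(abs(grid - attr(s_auto, "s0")) < 1e-12))
  expect_equal(s_auto$statistic,
               oracle_samt_given_s0(v, des$idx1, des$idx2, attr(s_auto, "s0")),
               tolerance = 1e-10)
})

test_that("the fudge factor demotes near-zero-variance non-DEG genes", {
  # genes with tiny variance and tiny difference get huge ordinary t but
  # modest samT: the stabilization the fudge factor exists for
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    m <- 200
    vals <- matrix(rnorm(m * 8, 8, 0.6), m)
    quiet <- 1:10
    vals[quiet, ] <- 8 + matrix(rnorm(10 * 8, 0, 0.005), 10)
    em <- make_em(vals, c(rep("A", 4), rep("B", 4)))
    des <- class_design(em, "A", "B")
    r_t <- rank_genes(sam_t(em, des, s0 = 0))$rank
    r_sam <- rank_genes(sam_t(em, des))$rank
    if (mean(r_sam[quiet]) > mean(r_t[quiet])) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("shrinkage t matches its direct-formula oracle and clamps lambda", {
  for (seed in c(41, 42)) {
    em <- random_em(m = 70, n1 = 4, n2 = 5, seed = seed)
    des <- class_design(em, "A", "B")
    s <- shrinkage_t(em, des)
    lam <- attr(s, "lambda")
    expect_gte(lam, 0); expect_lte(lam, 1)
    expect_equal(s$statistic, oracle_shrt(em$values, des$idx1, des$idx2),
                 tolerance = 1e-10)
  }
  em <- random_em(m = 50, seed = 43)
  des <- class_design(em, "A", "B")
  expect_equal(shrinkage_t(em, des, lambda = 0)$statistic,
               oracle_t(em$values, des$idx1, des$idx2), tolerance = 1e-10)
})

test_that("ibmT reduces to modT ranking when the variance trend is flat", {
  # variances drawn independently of intensity
  set.seed(51)
  m <- 300
  mu <- runif(m, 4, 14)
  sds <- sqrt(1 / rgamma(m, shape = 8, rate = 8)) * 0.4
  vals <- mu + matrix(rnorm(m * 10), m) * sds
  em <- make_em(vals, c(rep("A", 5), rep("B", 5)))
  des <- class_design(em, "A", "B")
  r_ibm <- rank_genes(ibm_t(em, des))$rank
  r_mod <- rank_genes(moderated_t(em, des))$rank
  expect_gt(cor(r_ibm, r_mod), 0.99)
})

test_that("a non-flat trend separates genes of equal difference and variance", {
  set.seed(52)
  m <- 200
  mu <- seq(4, 14, length.out = m)
  noise <- 0.2 + 0.1 * (14 - mu)   # dim genes noisier
  vals <- mu + matrix(rnorm(m * 8), m) * noise
  # two probes with identical difference and identical sample values up to
  # location: one dim, one bright
  probe_vals <- c(rep(0, 4), rep(1, 4)) + c(0.05, -0.05, 0.02, -0.02,
                                            0.05, -0.05, 0.02, -0.02)
  vals[1, ] <- 4 + probe_vals
  vals[2, ] <- 13 + probe_vals
  em <- make_em(vals, c(rep("A", 4), rep("B", 4)))
  des <- class_design(em, "A", "B")
  s <- ibm_t(em, des)
  expect_gt(abs(s$statistic[2]), abs(s$statistic[1]))
})

test_that("intensity-dependent noise favours ibmT over modT on average", {
  # Monte-Carlo over the generator's stated world at low replication:
  # steep intensity-variance trend, DEGs across the intensity range
  # (including the noisy dim end where the intensity prior matters)
  diffs <- vapply(1:20, function(i) {
    cfg <- sim_config(n_genes = 400, n_deg = 60, effect_size = 1.2,
                      noise_sd = 0.2, intensity_noise_slope = 0.08,
                      site_sd = 0, n_sites = 1, n_reps = 3,
                      platforms = list(platform_spec("P", 0, 0, 0)),
                      rtpcr_n_genes = 100, rtpcr_noise_sd = 0.1,
                      set_size_range = c(5, 50), seed = 60 + i)
    u <- generate_universe(cfg)
    ex <- generate_expression(cfg, u)
    em <- ex$matrices[[1]][[1]]
    des <- class_design(em, "A", "B")
    gt <- data.frame(gene = u$truth$gene, is_deg = u$truth$is_deg)
    ann <- ex$annotations[[1]]
    auc(rank_genes(ibm_t(em, des)), gt, map = ann) -
      auc(rank_genes(moderated_t(em, des)), gt, map = ann)
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("degenerate all-zero-variance input raises an informative error", {
  em <- make_em(matrix(rep(c(1, 2), each = 10), 5, 4, byrow = TRUE),
                c("A", "A", "B", "B"))
  em$values <- matrix(rep(c(1, 1, 2, 2), each = 5), 5, 4)
  des <- class_design(em, "A", "B")
  for (f in list(moderated_t, sam_t, shrinkage_t, ibm_t))
    expect_error(f(em, des), class = "degrank_input_error")
})
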