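test_that("LD scores match the brute-force all-pairs oracle on a toy panel", {
  p <- simulate_panel(sim_config(200, 20, block_size = 5,
                                 within_block_r = 0.5, seed = 1))
  anns <- synthetic_annotations(p, c(catA = 0.2), n_intervals = 2, seed = 1)
  ld <- compute_ld_scores(p, anns, window = 1e9)  # window >= chromosome span
  memb <- cbind(TRUE, annotation_membership(anns)[, "catA"])
  expect_equal(unname(ld$scores), oracle_ld_scores(p$dosages, memb),
               tolerance = 1e-10)
})

test_that("independent SNPs give base scores near one (self-term only)", {
  p <- simulate_panel(sim_config(10000, 300, block_size = 10,
                                 within_block_r = 0, seed = 2))
  ld <- compute_ld_scores(p, NULL, window = 1e9)
  expect_lt(max(abs(ld$scores[, "base"] - 1)), 0.1)
})

test_that("a block of perfectly correlated SNPs scores its block size", {
  set.seed(3)
  x <- rbinom(300, 2, 0.4)
  p <- toy_panel(rep(list(x), 5))
  ld <- compute_ld_scores(p, NULL, window = 1e9)
  expect_equal(unname(ld$scores[, "base"]), rep(5, 5), tolerance = 1e-12)
})

test_that("category scores never exceed the base score beyond the bias tolerance", {
  p <- simulate_panel(sim_config(500, 1000, block_size = 25,
                                 within_block_r = 0.5, seed = 4))
  anns <- synthetic_annotations(p, c(a = 0.1, b = 0.3), seed = 4)
  ld <- compute_ld_scores(p, anns, window = 1e5)
  for (cc in c("a", "b"))
    expect_true(all(ld$scores[, "base"] >= ld$scores[, cc] - 0.05))
  expect_error(compute_ld_scores(p, anns, window = -1), "window")
})

test_that("null traits give a unit intercept and heritability within noise of zero", {
  ints <- h2s <- covered <- numeric(10)
  for (s in 1:10) {
    cc <- sim_cohort(1000, 2000, h2 = 0, seed = 400 + s)
    ld <- compute_ld_scores(cc$panel, NULL, window = 5e4)
    fit <- fit_partitioned_h2(cc$stats, ld, n_blocks = 100)
    ints[s] <- fit$intercept; h2s[s] <- fit$h2_total
    covered[s] <- abs(fit$h2_total) <= 2 * fit$se_h2
  }
  # the strict calibration band belongs to the 100-replicate experiment in
  # the acceptance suite; 10 replicates get a looser band
  expect_gt(mean(ints), 0.9); expect_lt(mean(ints), 1.1)
  expect_gte(mean(covered), 0.8)
})

test_that("the all-SNPs category has enrichment exactly one with zero SE", {
  cc <- sim_cohort(800, 2000, h2 = 0.4, seed = 5)
  anns <- synthetic_annotations(cc$panel, c(cat = 0.1), seed = 5)
  ld <- compute_ld_scores(cc$panel, anns, window = 5e4)
  fit <- fit_partitioned_h2(cc$stats, ld, n_blocks = 100)
  base <- fit$categories[fit$categories$category == "base", ]
  expect_identical(base$enrichment, 1)
  expect_identical(base$se_enrichment, 0)
  expect_identical(base$prop_snps, 1)
})

test_that("univariate and base-only stratified code paths coincide", {
  cc <- sim_cohort(600, 1500, h2 = 0.5, seed = 6)
  ld_univ <- compute_ld_scores(cc$panel, NULL, window = 5e4)
  base_iv <- data.frame(chrom = "1", start = 0,
                        end = max(cc$panel$snps$pos) + 1)
  anns <- annotation_set(list(base = list(intervals = base_iv)),
                         cc$panel$snps)
  ld_strat <- compute_ld_scores(cc$panel, anns, window = 5e4)
  f1 <- fit_partitioned_h2(cc$stats, ld_univ, n_blocks = 100)
  f2 <- fit_partitioned_h2(cc$stats, ld_strat, n_blocks = 100)
  expect_equal(f1$h2_total, f2$h2_total, tolerance = 1e-10)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-10)
})

test_that("doubling the cohort shrinks the heritability SE by about root two", {
  # noise-dominated regime (low h2, loose LD) where the root-N scaling holds
  se_small <- se_big <- h2_small <- h2_big <- numeric(6)
  for (s in 1:6) {
    c1 <- sim_cohort(600, 4000, h2 = 0.2, seed = 500 + s,
                     within_block_r = 0.3)
    c2 <- sim_cohort(1200, 4000, h2 = 0.2, seed = 600 + s,
                     within_block_r = 0.3)
    f1 <- fit_partitioned_h2(c1$stats,
                             compute_ld_scores(c1$panel, NULL, window = 5e4),
                             n_blocks = 100)
    f2 <- fit_partitioned_h2(c2$stats,
                             compute_ld_scores(c2$panel, NULL, window = 5e4),
                             n_blocks = 100)
    se_small[s] <- f1$se_h2; se_big[s] <- f2$se_h2
    h2_small[s] <- f1$h2_total; h2_big[s] <- f2$h2_total
  }
  expect_lt(abs(mean(h2_small) - 0.2), 0.15)
  expect_lt(abs(mean(h2_big) - 0.2), 0.15)
  expect_gt(mean(se_small) / mean(se_big), 1.15)
  expect_lt(mean(se_small) / mean(se_big), 1.8)
})

test_that("stratified confounding inflates the regression intercept", {
  ints <- vapply(1:10, function(s) {
    cfg <- sim_config(1000, 5000, h2_total = 0.4, confound_strength = 0.02,
                      seed = 700 + s)
    p <- simulate_panel(cfg)
    ph <- simulate_phenotypes(p, NULL, cfg)
    st <- run_gwas(p, ph$values[, 1], ph$covariates)
    ld <- compute_ld_scores(p, NULL, window = 5e4)
    fit_partitioned_h2(st, ld, n_blocks = 100)$intercept
  }, numeric(1))
  expect_gte(sum(ints > 1), 9)
})

test_that("genetic correlation of a trait with itself is one", {
  cc <- sim_cohort(800, 2000, h2 = 0.5, seed = 7)
  ld <- compute_ld_scores(cc$panel, NULL, window = 5e4)
  r <- fit_rg(cc$stats, cc$stats, ld, n_blocks = 100)
  expect_equal(r$rg, 1.0, tolerance = 1e-6)
  expect_false(r$out_of_range)
})

test_that("independent architectures give a genetic correlation near zero", {
  within <- vapply(1:4, function(s) {
    cfg <- sim_config(800, 2000, h2_total = 0.5, seed = 800 + s)
    p <- simulate_panel(cfg)
    ph <- simulate_phenotypes(p, NULL, cfg, n_traits = 2, effect_cor = 0)
    s1 <- run_gwas(p, ph$values[, 1], ph$covariates)
    s2 <- run_gwas(p, ph$values[, 2], ph$covariates)
    ld <- compute_ld_scores(p, NULL, window = 5e4)
    r <- fit_rg(s1, s2, ld, n_blocks = 100)
    abs(r$rg) <= 2 * r$se_rg
  }, logical(1))
  expect_gte(sum(within), 3)
})

test_that("shared architecture recovers the planted genetic correlation", {
  rgs <- ses <- numeric(8)
  for (s in 1:8) {
    cfg <- sim_config(1500, 4000, h2_total = 0.5, seed = 900 + s)
    p <- simulate_panel(cfg)
    ph <- simulate_phenotypes(p, NULL, cfg, n_traits = 2, effect_cor = 0.5)
    s1 <- run_gwas(p, ph$values[, 1], ph$covariates)
    s2 <- run_gwas(p, ph$values[, 2], ph$covariates)
    ld <- compute_ld_scores(p, NULL, window = 5e4)
    r <- fit_rg(s1, s2, ld, n_blocks = 100)
    rgs[s] <- r$rg; ses[s] <- r$se_rg
  }
  expect_gte(sum(abs(rgs - 0.5) <= 2 * ses), 7)
  expect_lt(abs(mean(rgs) - 0.5), 0.15)
})

test_that("LD-score tables survive a TSV round trip of scores and counts", {
  cc <- sim_cohort(300, 200, seed = 8)
  anns <- synthetic_annotations(cc$panel, c(cat = 0.2), n_intervals = 4, seed = 8)
  ld <- compute_ld_scores(cc$panel, anns, window = 5e4)
  f <- tempfile(fileext = ".tsv")
  write_ld_scores(ld, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$base, unname(ld$scores[, "base"]), tolerance = 1e-6)
  mc <- read.table(paste0(f, ".M"), header = TRUE, sep = "\t")
  expect_equal(mc$M, unname(as.integer(ld$M_C)))
})
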