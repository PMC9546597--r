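test_that("panel dimensions, blocks, bounds and metadata are as configured", {
  p <- simulate_panel(sim_config(100, 50, block_size = 10, seed = 1))
  expect_equal(dim(p$dosages), c(100, 50))
  expect_equal(length(unique(p$block_map)), 5)
  expect_true(all(p$dosages %in% 0:2))
  expect_true(all(diff(p$snps$pos) > 0))
  expect_true(all(p$snps$info >= 0.4 & p$snps$info <= 1))
})

test_that("identical configurations give bit-identical cohorts", {
  cfg <- sim_config(150, 80, block_size = 20, within_block_r = 0.4,
                    confound_strength = 0.05, h2_total = 0.3, seed = 42)
  p1 <- simulate_panel(cfg); p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  ph1 <- simulate_phenotypes(p1, NULL, cfg)
  ph2 <- simulate_phenotypes(p2, NULL, cfg)
  expect_identical(ph1, ph2)
  s1 <- simulate_sds(p1, ph1$true_betas[, 1], cfg)
  s2 <- simulate_sds(p2, ph2$true_betas[, 1], cfg)
  expect_identical(s1, s2)
})

test_that("within-block dosage correlation is calibrated to its target", {
  # independence case: mean off-diagonal r ~ 0
  p0 <- simulate_panel(sim_config(2000, 200, block_size = 10,
                                  within_block_r = 0, seed = 3))
  C0 <- cor(p0$dosages)
  expect_lt(abs(mean(C0[upper.tri(C0)])), 3 / sqrt(2000))
  # calibrated case: latent-Gaussian -> binomial construction hits the target
  p6 <- simulate_panel(sim_config(2000, 500, block_size = 25,
                                  within_block_r = 0.6, seed = 4))
  rs <- unlist(lapply(1:20, function(b) {
    C <- cor(p6$dosages[, p6$block_map == b]); C[upper.tri(C)]
  }))
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("realized MAF stays within the configured range up to sampling error", {
  p <- simulate_panel(sim_config(1000, 400, maf_range = c(0.1, 0.4), seed = 5))
  f <- colMeans(p$dosages) / 2
  maf <- pmin(f, 1 - f)
  tol <- 3 * sqrt(0.4 * 0.6 / (2 * 1000))
  expect_true(all(maf >= 0.1 - tol & maf <= 0.4 + tol))
})

test_that("without confounding the leading PC is consistent with exchangeability", {
  # LD-free panel: with LD, the leading eigenvalue reflects SNP correlation
  # even under individual exchangeability
  p <- simulate_panel(sim_config(150, 300, block_size = 10,
                                 within_block_r = 0, seed = 6))
  lead_share <- function(X) {
    ev <- eigen(tcrossprod(scale(X, scale = FALSE)), symmetric = TRUE,
                only.values = TRUE)$values
    ev[1] / sum(ev)
  }
  obs <- lead_share(p$dosages)
  set.seed(7)
  perm <- replicate(20, lead_share(apply(p$dosages, 2, sample)))
  expect_lte(obs, max(perm) * 1.05)
})

test_that("stratified panels diverge in allele frequency between subpopulations", {
  cfg <- sim_config(800, 300, confound_strength = 0.1, seed = 8)
  p <- simulate_panel(cfg)
  expect_equal(sort(unique(p$subpop)), c(0L, 1L))
  d <- colMeans(p$dosages[p$subpop == 0, ]) - colMeans(p$dosages[p$subpop == 1, ])
  p0 <- simulate_panel(sim_config(800, 300, confound_strength = 0, seed = 8))
  d0 <- colMeans(p0$dosages[1:400, ]) - colMeans(p0$dosages[401:800, ])
  expect_gt(sd(d), 2 * sd(d0))
})

test_that("null-heritability phenotypes are independent of genotype", {
  # independent SNPs: under LD the mean-chi2 sampling noise triples
  cc <- sim_cohort(1000, 5000, h2 = 0, seed = 9, within_block_r = 0)
  expect_true(all(cc$pheno$true_betas == 0))
  expect_gt(mean(cc$stats$chi2), 0.95)
  expect_lt(mean(cc$stats$chi2), 1.05)
})

test_that("enrichment factors scale per-SNP effect variance by construction", {
  f <- 10
  cfg <- sim_config(500, 4000, h2_total = 0.5,
                    enrichment_factors = list(cat = f), seed = 10)
  p <- simulate_panel(cfg)
  anns <- synthetic_annotations(p, c(cat = 0.05), seed = 10)
  ph <- simulate_phenotypes(p, anns, cfg)
  m <- annotation_membership(anns)[, "cat"]
  sdx <- apply(p$dosages, 2, sd)
  b2 <- (ph$true_betas[, 1] * sdx)^2   # standardized scale
  ratio <- mean(b2[m]) / mean(b2[!m])
  expect_gt(ratio, 7); expect_lt(ratio, 13)
  expect_error(simulate_phenotypes(
    p, anns, sim_config(500, 4000, enrichment_factors = list(cat = -1),
                        seed = 1)))
})

test_that("realized narrow-sense heritability matches its target", {
  shares <- vapply(1:5, function(seed) {
    cc <- sim_cohort(2000, 5000, h2 = 0.5, seed = 100 + seed)
    g <- cc$panel$dosages %*% cc$pheno$true_betas
    summary(lm(cc$pheno$values[, 1] ~ g))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.5), 0.05)
})

test_that("null SDS is uncorrelated with association strength", {
  cc <- sim_cohort(500, 10000, h2 = 0.4, seed = 11)
  sds <- simulate_sds(cc$panel, cc$pheno$true_betas[, 1], cc$cfg)
  m <- align_tsds(cc$stats, sds)
  expect_lt(abs(cor(m$tsds, m$z_inc, method = "spearman")), 3 / sqrt(10000))
})

test_that("selection coupling recovers the target rank correlation", {
  rec <- vapply(1:20, function(seed) {
    cfg <- sim_config(500, 10000, h2_total = 0.5, sds_selection_rho = 0.1,
                      seed = 200 + seed)
    p <- simulate_panel(cfg)
    ph <- simulate_phenotypes(p, NULL, cfg)
    sds <- simulate_sds(p, ph$true_betas[, 1], cfg)
    bm <- evoanno:::marginal_effects(p, ph$true_betas[, 1])
    tsds_true <- sds$sds * ifelse(bm >= 0, 1, -1)
    cor(tsds_true, abs(bm), method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rec) - 0.1), 0.03)
})

test_that("SDS dropout retains exactly the configured SNP count", {
  cfg <- sim_config(200, 1000, seed = 12)
  p <- simulate_panel(cfg)
  ph <- simulate_phenotypes(p, NULL, cfg)
  sds <- simulate_sds(p, ph$true_betas[, 1], cfg, dropout = 0.2)
  expect_equal(nrow(sds), ceiling(0.8 * 1000))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(0, 10), "dimensions")
  expect_error(sim_config(10, 10, within_block_r = 1), "within_block_r")
  expect_error(sim_config(10, 10, maf_range = c(0.4, 0.1)), "ordered")
  expect_error(sim_config(10, 10, h2_total = 1.5), "h2_total")
  expect_error(sim_config(10, 10, sds_selection_rho = 2), "sds_selection_rho")
  expect_error(sim_config(10, 10, enrichment_factors = list(a = 0)), "positive")
})
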