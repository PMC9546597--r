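sds_table_from <- function(ids, derived, sds, pos = NULL) {
  out <- data.frame(id = ids, chrom = "1",
                    pos = if (is.null(pos)) seq_along(ids) * 1000L else pos,
                    derived_allele = derived, sds = sds,
                    stringsAsFactors = FALSE)
  class(out) <- c("sds_table", "data.frame")
  out
}

test_that("alignment orients SDS to the trait-increasing allele", {
  st <- make_stats(beta = c(0.5, -0.5, 0.5, 0.5))
  st$allele_effect <- c("A", "A", "A", "A")
  st$allele_other <- c("G", "G", "G", "G")
  sds <- sds_table_from(st$id,
                        derived = c("A", "A", "G", "T"),
                        sds = c(1, 1, 1, 1))
  m <- align_tsds(st, sds)
  # SNP1: effect == derived, beta > 0 -> tsds = +sds
  expect_equal(m$tsds[m$id == st$id[1]], 1)
  # SNP2: effect == derived but beta < 0 -> trait-increasing orientation flips
  expect_equal(m$tsds[m$id == st$id[2]], -1)
  # SNP3: derived matches the other allele -> sds flipped, beta > 0
  expect_equal(m$tsds[m$id == st$id[3]], -1)
  # SNP4: A/G stats vs T derived = complement of effect allele -> aligned
  expect_equal(m$tsds[m$id == st$id[4]], 1)
  expect_equal(attr(m, "n_dropped_alleles"), 0)
})

test_that("irreconcilable allele pairs are dropped with a logged count", {
  # a palindromic A/T pair reconciles only with A or T: derived C is dropped
  st <- make_stats(beta = c(1, 1))
  st$allele_effect <- c("A", "A"); st$allele_other <- c("T", "T")
  sds <- sds_table_from(st$id, derived = c("A", "C"), sds = c(1, 1))
  expect_message(m <- align_tsds(st, sds), "1 SNP")
  expect_equal(nrow(m), 1)
  expect_equal(attr(m, "n_dropped_alleles"), 1)
})

test_that("the merge is an inner join sorted by position", {
  set.seed(1)
  st <- make_stats(rnorm(1000))
  keep <- sort(sample(1000, 800))
  sds <- sds_table_from(st$id[keep], derived = "A", sds = rnorm(800),
                        pos = st$pos[keep])
  m <- align_tsds(st[sample(1000), ], sds)
  expect_equal(nrow(m), 800)
  expect_false(is.unsorted(m$pos))
})

test_that("a monotone tSDS-Z relation gives correlation one", {
  set.seed(2)
  st <- make_stats(rnorm(500))
  sds <- sds_table_from(st$id, "A", sds = rank(abs(st$z)) * sign(st$beta),
                        pos = st$pos)
  m <- align_tsds(st, sds)
  r <- tsds_test(m, n_blocks = 50)
  expect_equal(r$rho, 1.0, tolerance = 1e-12)
})

test_that("jackknife blocks are contiguous equal slices of the SNP list", {
  b <- evoanno:::block_assign(1000, 100)
  expect_equal(as.integer(table(b)), rep(10L, 100))
  expect_true(all(diff(b) >= 0))
  b2 <- evoanno:::block_assign(1005, 100)
  expect_equal(sum(b2 == 100), 15)  # last block absorbs the remainder
})

test_that("the test rejects degenerate and undersized inputs", {
  st <- make_stats(rep(1, 200))
  sds <- sds_table_from(st$id, "A", rep(0.5, 200), pos = st$pos)
  m <- align_tsds(st, sds)
  expect_error(tsds_test(m, 100), "degenerate")
  st2 <- make_stats(rnorm(50))
  m2 <- align_tsds(st2, sds_table_from(st2$id, "A", rnorm(50), pos = st2$pos))
  expect_error(tsds_test(m2, 100), "fewer SNPs")
})

test_that("permuting tSDS destroys a planted selection signal", {
  cfg <- sim_config(1000, 8000, h2_total = 0.5, sds_selection_rho = 0.15,
                    seed = 3)
  p <- simulate_panel(cfg)
  ph <- simulate_phenotypes(p, NULL, cfg)
  st <- run_gwas(p, ph$values[, 1], ph$covariates)
  sds <- simulate_sds(p, ph$true_betas[, 1], cfg)
  m <- align_tsds(st, sds)
  expect_lt(tsds_test(m)$p, 0.05)
  set.seed(4)
  m_perm <- m
  m_perm$tsds <- sample(m$tsds)
  expect_gt(tsds_test(m_perm)$p, 0.05)
})

test_that("the result is invariant to joint sign flips of beta and SDS", {
  set.seed(5)
  st <- make_stats(rnorm(600))
  sds <- sds_table_from(st$id, "A", rnorm(600), pos = st$pos)
  r1 <- tsds_test(align_tsds(st, sds), 60)
  flip <- sample(c(TRUE, FALSE), 600, replace = TRUE)
  st2 <- st
  st2$beta[flip] <- -st2$beta[flip]
  st2$z[flip] <- -st2$z[flip]
  sds2 <- sds
  sds2$sds[flip] <- -sds2$sds[flip]
  r2 <- tsds_test(align_tsds(st2, sds2), 60)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$se_jack, r2$se_jack, tolerance = 1e-12)
})

test_that("SDS tables survive a TSV round trip", {
  cfg <- sim_config(100, 200, seed = 6)
  p <- simulate_panel(cfg)
  ph <- simulate_phenotypes(p, NULL, cfg)
  sds <- simulate_sds(p, ph$true_betas[, 1], cfg)
  f <- tempfile(fileext = ".tsv")
  write_sds(sds, f)
  back <- read_sds(f)
  expect_equal(back$sds, sds$sds, tolerance = 1e-12)
  expect_equal(back$derived_allele, sds$derived_allele)
})
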