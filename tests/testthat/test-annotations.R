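iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

test_that("interval merging coalesces overlaps and book-ends, keeps disjoint", {
  m1 <- merge_intervals(list(iv("1", 100, 200), iv("1", 150, 250)))
  expect_equal(m1, iv("1", 100, 250))
  m2 <- merge_intervals(list(iv("1", 100, 200), iv("1", 300, 400)))
  expect_equal(m2$start, c(100, 300)); expect_equal(m2$end, c(200, 400))
  m3 <- merge_intervals(list(iv("1", 100, 200), iv("1", 200, 300)))
  expect_equal(m3, iv("1", 100, 300))
  expect_error(merge_intervals(iv("1", 200, 200)), "start >= end")
})

test_that("interval merging is idempotent and order-invariant", {
  set.seed(1)
  sets <- lapply(1:3, function(i)
    iv("1", s <- sort(sample(1000, 5)) * 10, s * 10 + sample(40, 5)))
  m <- merge_intervals(sets)
  expect_equal(merge_intervals(m), m)
  expect_equal(merge_intervals(rev(sets)), m)
})

test_that("membership uses half-open semantics on 1-based SNP positions", {
  snps <- data.frame(id = paste0("s", 1:4), chrom = "1",
                     pos = c(1000, 1001, 2000, 2001))
  anns <- annotation_set(list(cat = list(intervals = iv("1", 1000, 2000))),
                         snps)
  memb <- annotation_membership(anns)[, "cat"]
  # inside iff start <= pos-1 < end
  expect_equal(unname(memb), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("merging developmental stages raises coverage above any single stage", {
  p <- simulate_panel(sim_config(100, 2000, seed = 2))
  stages <- lapply(c(3, 5, 7), function(off) {
    starts <- (seq(off, 1900, by = 400) - 1) * 1000
    iv("1", starts, starts + 10 * 1000)   # ~0.5% each, partially overlapping
  })
  singles <- vapply(stages, function(s)
    snp_coverage(list(intervals = s), p$snps)$fraction, numeric(1))
  merged <- snp_coverage(list(intervals = merge_intervals(stages)), p$snps)
  expect_gt(merged$fraction, max(singles))
})

test_that("LD expansion finds perfect proxies and matches the brute-force oracle", {
  set.seed(3)
  x <- rbinom(400, 2, 0.3)
  cols <- c(list(x, x), lapply(1:4, function(i) rbinom(400, 2, 0.3)))
  p <- toy_panel(cols)
  out <- ld_expand(p$snps$id[1], p, r2_min = 1)
  expect_setequal(out, p$snps$id[1:2])
  lone <- ld_expand(p$snps$id[3], p, r2_min = 0.99)
  expect_equal(lone, p$snps$id[3])

  p50 <- simulate_panel(sim_config(300, 50, block_size = 10,
                                   within_block_r = 0.8,
                                   maf_range = c(0.3, 0.5), seed = 4))
  seed_ids <- p50$snps$id[c(5, 25)]
  got <- ld_expand(seed_ids, p50, r2_min = 0.6)
  want <- p50$snps$id[oracle_ld_expand(c(5, 25), p50$dosages, 0.6)]
  expect_setequal(got, want)
})

test_that("LD expansion is a superset of its input and monotone in the threshold", {
  p <- simulate_panel(sim_config(300, 60, block_size = 15,
                                 within_block_r = 0.7, seed = 5))
  ids <- p50_ids <- p$snps$id[c(3, 33)]
  prev <- NULL
  for (r2 in c(0.9, 0.6, 0.3)) {
    out <- ld_expand(ids, p, r2_min = r2)
    expect_true(all(ids %in% out))
    if (!is.null(prev)) expect_true(all(prev %in% out))
    prev <- out
  }
  expect_error(ld_expand("nope", p, 0.5), "unknown SNP ids")
})

test_that("desert refinement removes introgressed SNPs and their LD partners", {
  set.seed(6)
  x <- rbinom(500, 2, 0.4)
  flip <- function(v, k) { i <- sample(500, k); v[i] <- 2 - v[i]; v }
  cols <- list(x, flip(x, 10), flip(x, 12),       # SNPs 1-3: tight LD
               rbinom(500, 2, 0.4), rbinom(500, 2, 0.4),
               rbinom(500, 2, 0.4))
  p <- toy_panel(cols)
  deserts <- iv("1", 0, 5000)  # SNPs 1-5 inside, SNP 6 outside
  cat_none <- refine_deserts(deserts, introgressed = character(0), panel = p)
  expect_setequal(cat_none$snp_ids, p$snps$id[1:5])

  cat_one <- refine_deserts(deserts, introgressed = p$snps$id[1], panel = p)
  expect_setequal(cat_one$excluded_snp_ids, p$snps$id[1:3])
  expect_setequal(cat_one$snp_ids, p$snps$id[4:5])
  expect_length(intersect(cat_one$snp_ids, p$snps$id[1]), 0)

  cat_out <- refine_deserts(deserts, introgressed = p$snps$id[6], panel = p)
  expect_setequal(cat_out$snp_ids, p$snps$id[1:5])
})

test_that("coverage reports apply the inclusive one-percent rule", {
  ref <- data.frame(id = sprintf("r%05d", 1:10000), chrom = "1",
                    pos = (1:10000) * 1000)
  rep150 <- snp_coverage(list(snp_ids = ref$id[1:150]), ref)
  expect_equal(rep150$fraction, 0.015); expect_true(rep150$passes_threshold)
  rep50 <- snp_coverage(list(snp_ids = ref$id[1:50]), ref)
  expect_equal(rep50$fraction, 0.005); expect_false(rep50$passes_threshold)
  rep100 <- snp_coverage(list(snp_ids = ref$id[1:100]), ref)
  expect_equal(rep100$fraction, 0.01); expect_true(rep100$passes_threshold)
  expect_error(snp_coverage(list(snp_ids = "x"), ref[0, ]), "empty reference")
})

test_that("BED files and SNP lists survive round trips", {
  ivs <- iv("1", c(100, 500), c(200, 900))
  f <- tempfile(fileext = ".bed")
  write_bed(ivs, f)
  expect_equal(read_bed(f), ivs)
  g <- tempfile(fileext = ".txt")
  write_snp_list(c("rs1", "rs2"), g)
  expect_equal(read_snp_list(g), c("rs1", "rs2"))
})
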