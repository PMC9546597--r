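# Small fixtures built in code.

# Hand-built panel: dosage columns supplied directly, 1 kb SNP spacing.
toy_panel <- function(dosage_cols, info = NULL, multiallelic = NULL,
                      block_map = NULL) {
  dos <- do.call(cbind, dosage_cols)
  M <- ncol(dos)
  snps <- data.frame(
    id = sprintf("toy%03d", seq_len(M)), chrom = "1",
    pos = (seq_len(M) - 1L) * 1000L + 1L,
    allele_other = rep("G", M), allele_effect = rep("A", M),
    maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
    info = if (is.null(info)) rep(1, M) else info,
    multiallelic = if (is.null(multiallelic)) rep(FALSE, M) else multiallelic,
    derived_is_effect = TRUE, stringsAsFactors = FALSE
  )
  genotype_panel(dos, snps,
                 block_map = if (is.null(block_map)) rep(1L, M) else block_map)
}

# Synthetic summary statistics with given betas/ses on a 1 kb grid.
make_stats <- function(beta, se = rep(1, length(beta)), n = 1000,
                       p = NULL, chrom = "1") {
  M <- length(beta)
  z <- beta / se
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    id = sprintf("rs%06d", seq_len(M)), chrom = chrom,
    pos = (seq_len(M) - 1L) * 1000L + 1L,
    allele_effect = "A", allele_other = "G",
    beta = beta, se = se, z = z, chi2 = z^2, p = p, n = n,
    missing = FALSE, stringsAsFactors = FALSE
  )
  class(out) <- c("sumstats", "data.frame")
  out
}

# A simulated cohort scanned end to end: panel, phenotypes, sumstats.
sim_cohort <- function(n, m, h2 = 0.4, seed = 1, ...) {
  cfg <- sim_config(n, m, h2_total = h2, seed = seed, ...)
  panel <- simulate_panel(cfg)
  pheno <- simulate_phenotypes(panel, NULL, cfg)
  stats <- run_gwas(panel, pheno$values[, 1], pheno$covariates)
  list(cfg = cfg, panel = panel, pheno = pheno, stats = stats)
}
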