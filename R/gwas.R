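# Subset a genotype panel to a set of SNP column indices, preserving order.
subset_panel <- function(panel, idx) {
  new_genotype_panel(panel$dosages[, idx, drop = FALSE],
                     panel$snps[idx, , drop = FALSE],
                     panel$block_map[idx],
                     panel$subpop)
}

#' Variant quality control
#'
#' Retains biallelic SNPs with realized minor allele frequency >= `maf_min`,
#' Hardy-Weinberg equilibrium p-value >= `hwe_p_min` (1-df chi-square on
#' genotype counts hard-called by rounding dosages), and imputation INFO
#' score >= `info_min`. Multiallelic SNPs are excluded regardless of other
#' fields. SNP order is preserved and the operation is idempotent. Defaults
#' are the conventional imputed-data thresholds (MAF 0.1%, HWE 1e-6,
#' INFO 0.7).
#'
#' @param panel A `genotype_panel`.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum HWE p-value.
#' @param info_min Minimum imputation INFO score.
#' @return The filtered `genotype_panel`, with attribute `qc_log` recording
#'   SNP counts in/out per filter.
#' @export
qc_variants <- function(panel, maf_min = 0.001, hwe_p_min = 1e-6,
                        info_min = 0.7) {
  stopifnot(inherits(panel, "genotype_panel"))
  M <- n_snps(panel)
  if (M == 0) stop("empty panel", call. = FALSE)

  freq <- colMeans(panel$dosages) / 2
  maf_hat <- pmin(freq, 1 - freq)

  hard <- round(panel$dosages)
  n <- nrow(hard)
  n2 <- colSums(hard == 2); n1 <- colSums(hard == 1); n0 <- n - n1 - n2
  p_hat <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - p_hat)^2; e1 <- n * 2 * p_hat * (1 - p_hat); e2 <- n * p_hat^2
  chi2 <- rep(0, M)
  ok <- e0 > 0 & e1 > 0 & e2 > 0
  chi2[ok] <- ((n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)[ok]
  hwe_p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)

  pass_maf <- maf_hat >= maf_min
  pass_hwe <- hwe_p >= hwe_p_min
  pass_info <- panel$snps$info >= info_min
  pass_bi <- !panel$snps$multiallelic
  keep <- pass_maf & pass_hwe & pass_info & pass_bi
  if (!any(keep)) stop("variant QC removed all SNPs", call. = FALSE)

  out <- subset_panel(panel, which(keep))
  attr(out, "qc_log") <- data.frame(
    filter = c("input", "maf", "hwe", "info", "biallelic", "retained"),
    n = c(M, sum(!pass_maf), sum(!pass_hwe), sum(!pass_info), sum(!pass_bi),
          sum(keep))
  )
  out
}

#' Per-SNP additive-model association scan
#'
#' Standardizes the trait to zero mean and unit variance, residualizes trait
#' and dosages on the covariates once, then fits the per-SNP simple ordinary
#' least-squares regression of residualized trait on residualized dosage
#' (numerically equivalent to the full multiple regression for fixed
#' covariates, at O(NM) cost). Standard errors use N - K - 1 degrees of
#' freedom; p-values come from the t reference for small cohorts and the
#' normal reference for N > 200.
#'
#' @param panel A `genotype_panel` (typically after [qc_variants()]).
#' @param trait Numeric vector, one value per individual.
#' @param covariates Numeric matrix with one row per individual; an intercept
#'   column is added if absent. NULL means intercept only.
#' @param control_global Optional extra control column (e.g. the matching
#'   total hemispheric measure when scanning a regional trait); appended to
#'   the covariates.
#' @return A `sumstats` data frame: id, chrom, pos, allele_effect,
#'   allele_other, beta, se, z, chi2, p, n. Constant-dosage SNPs are emitted
#'   with beta 0, se Inf and a `missing` flag.
#' @export
run_gwas <- function(panel, trait, covariates = NULL, control_global = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  N <- n_individuals(panel)
  trait <- as.numeric(trait)
  stopifnot(length(trait) == N, all(is.finite(trait)))

  C <- if (is.null(covariates)) matrix(1, N, 1) else as.matrix(covariates)
  stopifnot(nrow(C) == N)
  if (!any(apply(C, 2, function(x) all(x == x[1]) && x[1] != 0)))
    C <- cbind(1, C)
  if (!is.null(control_global)) C <- cbind(C, as.numeric(control_global))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("rank-deficient covariate matrix", call. = FALSE)
  K <- ncol(C)
  Q <- qr.Q(qrC)

  y <- (trait - mean(trait)) / stats::sd(trait)
  y <- y - Q %*% crossprod(Q, y)

  G <- panel$dosages
  B <- crossprod(Q, G)                     # K x M
  xx <- numeric(ncol(G))
  chunk <- 4000L
  for (i in seq(1L, ncol(G), by = chunk)) {
    j <- i:min(ncol(G), i + chunk - 1L)
    xx[j] <- colSums(G[, j, drop = FALSE]^2)
  }
  xx <- xx - colSums(B^2)                  # residualized sum of squares
  xy <- as.numeric(crossprod(G, y))        # x' y_r == x_r' y_r

  yy <- sum(y^2)
  df <- N - K - 1
  const <- xx < 1e-10
  beta <- ifelse(const, 0, xy / pmax(xx, 1e-300))
  rss <- pmax(yy - beta * xy, 0)
  se <- ifelse(const, Inf, sqrt(rss / df / pmax(xx, 1e-300)))
  z <- ifelse(const, 0, beta / se)
  p <- if (N > 200) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df)
  p[const] <- NA_real_
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- data.frame(
    id = panel$snps$id,
    chrom = panel$snps$chrom,
    pos = panel$snps$pos,
    allele_effect = panel$snps$allele_effect,
    allele_other = panel$snps$allele_other,
    beta = beta,
    se = se,
    z = z,
    chi2 = z^2,
    p = p,
    n = N,
    missing = const,
    stringsAsFactors = FALSE
  )
  class(out) <- c("sumstats", "data.frame")
  attr(out, "ancestry_regressed") <- FALSE
  out
}

#' Write / read summary statistics in an LDSC-compatible TSV dialect
#'
#' Header: SNP CHR BP A1 A2 BETA SE Z P N (A1 = effect allele).
#'
#' @param stats A `sumstats` data frame.
#' @param path Output path (".gz" suffix gzips).
#' @return `read_sumstats` returns a `sumstats` data frame.
#' @export
write_sumstats <- function(stats, path) {
  df <- data.frame(SNP = stats$id, CHR = stats$chrom, BP = stats$pos,
                   A1 = stats$allele_effect, A2 = stats$allele_other,
                   BETA = stats$beta, SE = stats$se, Z = stats$z,
                   P = stats$p, N = stats$n)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(
    id = df$SNP, chrom = as.character(df$CHR), pos = df$BP,
    allele_effect = df$A1, allele_other = df$A2,
    beta = df$BETA, se = df$SE, z = df$Z, chi2 = df$Z^2,
    p = df$P, n = df$N, missing = !is.finite(df$SE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sumstats", "data.frame")
  out
}
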