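# ---- latent-correlation calibration -----------------------------------------

# Lower orthant probability P(Z1 < q1, Z2 < q2) for standard bivariate normal
# with correlation r, by one-dimensional quadrature. Accurate to ~1e-8; enough
# for calibrating a correlation to two decimals.
bvn_lower <- function(q1, q2, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(q1) * stats::pnorm(q2))
  s <- sqrt(1 - r^2)
  stats::integrate(function(z) stats::dnorm(z) * stats::pnorm((q2 - r * z) / s),
                   lower = -8.5, upper = q1, rel.tol = 1e-9)$value
}

# Phi coefficient (correlation of the two threshold indicators) for latent
# correlation r and marginal probabilities implied by thresholds a, b.
phi_coef <- function(a, b, r) {
  p1 <- stats::pnorm(a); p2 <- stats::pnorm(b)
  (bvn_lower(a, b, r) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Two cut points turning one latent normal into a binomial(2, p) dosage under
# Hardy-Weinberg proportions: dosage = 1(L < q2) + 1(L < q1),
# q2 = qnorm(p^2) (homozygote), q1 = qnorm(1 - (1-p)^2) (carrier).
dosage_cuts <- function(p) {
  list(q1 = stats::qnorm(1 - (1 - p)^2), q2 = stats::qnorm(p^2))
}

# Correlation of two such dosages under latent correlation r;
# Var(dosage) = 2 p (1 - p) by Hardy-Weinberg.
dosage_corr <- function(p1, p2, r) {
  c1 <- dosage_cuts(p1); c2 <- dosage_cuts(p2)
  exy <- bvn_lower(c1$q1, c2$q1, r) + bvn_lower(c1$q1, c2$q2, r) +
    bvn_lower(c1$q2, c2$q1, r) + bvn_lower(c1$q2, c2$q2, r)
  (exy - 4 * p1 * p2) / sqrt(4 * p1 * (1 - p1) * p2 * (1 - p2))
}

# Mean dosage correlation (over a deterministic quantile-midpoint grid of
# MAF pairs) as a function of the latent correlation, tabulated once so that
# per-block targets can be inverted by monotone interpolation.
latent_curve <- function(maf_range, grid_n = 8) {
  d <- diff(maf_range) / grid_n
  mids <- if (d > 0)
    seq(maf_range[1] + d / 2, maf_range[2] - d / 2, length.out = grid_n)
  else maf_range[1]
  pairs <- expand.grid(a = mids, b = mids)
  pairs <- pairs[pairs$a <= pairs$b, ]
  pairs <- rbind(pairs, pairs[pairs$a < pairs$b, ])  # unordered-pair weights
  lat <- c(seq(0, 0.9, by = 0.1), 0.95, 0.975, 0.999)
  meanr <- vapply(lat, function(r)
    mean(mapply(dosage_corr, pairs$a, pairs$b, MoreArgs = list(r = r))),
    numeric(1))
  meanr[1] <- 0
  list(lat = lat, meanr = meanr, max_r = meanr[length(meanr)])
}

# Invert the curve: latent correlation achieving each target dosage
# correlation.
latent_r_for <- function(target, curve) {
  if (any(target > curve$max_r))
    stop("within_block_r unattainable for this maf_range (threshold attenuation)",
         call. = FALSE)
  out <- stats::approx(curve$meanr, curve$lat, xout = pmax(target, 0),
                       rule = 2)$y
  out[target <= 0] <- 0
  out
}

# ---- genotype panel ---------------------------------------------------------

new_genotype_panel <- function(dosages, snps, block_map, subpop = NULL) {
  stopifnot(ncol(dosages) == nrow(snps), length(block_map) == nrow(snps))
  structure(list(dosages = dosages, snps = snps, block_map = block_map,
                 subpop = subpop),
            class = "genotype_panel")
}

#' Construct a genotype panel from a dosage matrix and SNP metadata
#'
#' For assembling panels from external data or hand-built fixtures. Missing
#' metadata columns get defaults (INFO 1, biallelic, derived = effect
#' allele); dosages must lie in `[0, 2]` and positions must be strictly
#' increasing within a chromosome.
#'
#' @param dosages N x M numeric matrix of allele dosages in `[0, 2]`.
#' @param snps Data frame with at least id, chrom, pos; optional
#'   allele_effect, allele_other, maf, info, multiallelic,
#'   derived_is_effect.
#' @param block_map Optional SNP -> LD-block index (default: one block).
#' @param subpop Optional 0/1 subpopulation label per individual.
#' @return A `genotype_panel`.
#' @export
genotype_panel <- function(dosages, snps, block_map = NULL, subpop = NULL) {
  dosages <- as.matrix(dosages)
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]", call. = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(snps)))
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop("SNP positions must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  M <- nrow(snps)
  defaults <- list(allele_effect = rep("A", M), allele_other = rep("G", M),
                   maf = pmin(colMeans(dosages) / 2, 1 - colMeans(dosages) / 2),
                   info = rep(1, M), multiallelic = rep(FALSE, M),
                   derived_is_effect = rep(TRUE, M))
  for (nm in names(defaults))
    if (is.null(snps[[nm]])) snps[[nm]] <- defaults[[nm]]
  if (is.null(block_map)) block_map <- rep(1L, M)
  new_genotype_panel(dosages, snps, block_map, subpop)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs, %d LD blocks%s\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$block_map)),
              if (is.null(x$subpop)) "" else ", 2 subpopulations"))
  invisible(x)
}

#' Number of individuals / SNPs in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_individuals <- function(panel) nrow(panel$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(panel) ncol(panel$dosages)

#' Simulate a genotype dosage panel with LD-block structure
#'
#' Genotypes are built from a latent multivariate normal with exchangeable
#' within-block correlation, thresholded per haplotype to give binomial(2, p)
#' dosages. The latent correlation is calibrated numerically so the *dosage*
#' correlation within a block matches `config$within_block_r`. SNPs sit on one
#' synthetic chromosome at fixed 1 kb spacing; imputation INFO scores are
#' drawn uniform(0.4, 1) so downstream QC has work to do. With
#' `confound_strength > 0` the cohort splits into two equal subpopulations
#' whose allele frequencies diverge under a Balding–Nichols model with
#' Fst = `confound_strength`.
#'
#' The derived allele is identified with the effect (counted) allele, which
#' fixes the SDS alignment convention deterministically in synthetic data.
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel`: list with `dosages` (N x M matrix in `[0, 2]`),
#'   `snps` (per-SNP metadata data frame), `block_map` (SNP -> block index),
#'   and `subpop` (0/1 per individual, or NULL).
#' @examples
#' panel <- simulate_panel(sim_config(200, 100, block_size = 20, seed = 7))
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  N <- config$n_individuals; M <- config$n_snps; bs <- config$block_size

  maf <- stats::runif(M, config$maf_range[1], config$maf_range[2])
  info <- stats::runif(M, 0.4, 1.0)
  nts <- c("A", "C", "G", "T")
  a_eff <- sample(nts, M, replace = TRUE)
  a_oth <- vapply(a_eff, function(a) sample(setdiff(nts, a), 1), character(1))
  snps <- data.frame(
    id = sprintf("rs%06d", seq_len(M)),
    chrom = "1",
    pos = (seq_len(M) - 1L) * 1000L + 1L,
    allele_other = a_oth,
    allele_effect = a_eff,
    maf = maf,
    info = info,
    multiallelic = FALSE,
    derived_is_effect = TRUE,
    stringsAsFactors = FALSE
  )
  block_map <- rep(seq_len(ceiling(M / bs)), each = bs)[seq_len(M)]

  Fst <- config$confound_strength
  subpop <- NULL
  if (Fst > 0) {
    subpop <- rep(c(0L, 1L), length.out = N)
    pfreq <- rbind(
      stats::rbeta(M, maf * (1 - Fst) / Fst, (1 - maf) * (1 - Fst) / Fst),
      stats::rbeta(M, maf * (1 - Fst) / Fst, (1 - maf) * (1 - Fst) / Fst)
    )
    pfreq <- pmin(pmax(pfreq, 1e-4), 1 - 1e-4)
  }

  # Heterogeneous LD: per-block target dosage correlations drawn uniformly
  # around within_block_r (symmetric spread, so the mean is exact). Real
  # genomes mix tight and loose LD; the spread also gives the LD-score
  # regression design genuine leverage.
  n_blocks <- max(block_map)
  rbar <- config$within_block_r
  curve <- latent_curve(config$maf_range)
  spread <- min(0.3, rbar, max(curve$max_r - 0.02 - rbar, 0))
  rb <- if (rbar > 0)
    stats::runif(n_blocks, rbar - spread, rbar + spread) else rep(0, n_blocks)
  rl <- latent_r_for(rb, curve)

  # one latent normal per genotype; two cut points give binomial(2, p) under
  # Hardy-Weinberg proportions: dosage = 1(L < q_carrier) + 1(L < q_hom)
  pop_p <- if (Fst > 0) pfreq else rbind(maf, maf)
  thr1 <- matrix(stats::qnorm(1 - (1 - pop_p)^2), 2, M)
  thr2 <- matrix(stats::qnorm(pop_p^2), 2, M)
  sp <- if (is.null(subpop)) integer(N) else subpop
  dos <- cpp_simulate_dosages(N, thr1, thr2, sp, as.integer(block_map),
                              sqrt(rl), sqrt(1 - rl))
  new_genotype_panel(dos, snps, block_map, subpop)
}

# Column means and population sds, one streaming pass.
col_moments <- function(X) {
  m <- cpp_col_moments(X)
  list(mean = as.numeric(m$mean), sd = as.numeric(m$sd))
}

# Marginal per-standardized-SNP effects implied by a causal effect vector:
# correlation of each standardized dosage with the standardized genetic value.
marginal_effects <- function(panel, true_betas) {
  mom <- col_moments(panel$dosages)
  Gs <- cpp_standardize(panel$dosages, mom$mean, mom$sd, 1e-12)
  g <- as.numeric(cpp_genetic_values(panel$dosages,
                                     matrix(true_betas, ncol = 1)))
  g <- g - mean(g)
  sg <- stats::sd(g)
  if (sg == 0) return(numeric(ncol(Gs)))
  as.numeric(crossprod(Gs, g)) / (length(g) * sg)
}

#' Simulate annotation-stratified polygenic phenotypes
#'
#' Draws per-SNP effects `beta_j ~ N(0, sigma2_j)` where `sigma2_j` is 1 for
#' background SNPs and multiplied by the configured enrichment factor for every
#' category containing SNP j (factors compose additively over overlapping
#' categories). The genetic component is rescaled so the realized narrow-sense
#' heritability equals `config$h2_total` exactly in-sample; environmental noise
#' has variance `1 - h2_total`. When the panel carries subpopulation labels, a
#' confound term is added so subpopulation membership explains a fraction
#' `confound_strength` of phenotypic variance (on top of the genetic and
#' environmental parts).
#'
#' @param panel A `genotype_panel`.
#' @param annotations An `annotation_set` resolved against the panel SNPs, or
#'   NULL for a homogeneous architecture.
#' @param config A [sim_config()]; `h2_total` and `enrichment_factors` are
#'   consumed here. Category names in `enrichment_factors` must exist in
#'   `annotations`.
#' @param n_traits Number of traits to simulate.
#' @param effect_cor Correlation of per-SNP effects between every trait pair
#'   (shared architecture); the true genetic correlation of the traits.
#' @param n_covariates Number of generic nuisance covariates (each receives a
#'   small fixed coefficient of 0.1 on every trait); an intercept column is
#'   always present.
#' @return A `phenotype_matrix`: list with `values` (N x T), `trait_names`,
#'   `covariates` (N x K, first column intercept), and `true_betas` (M x T).
#' @export
simulate_phenotypes <- function(panel, annotations = NULL, config,
                                n_traits = 1, effect_cor = 0,
                                n_covariates = 0) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  N <- n_individuals(panel); M <- n_snps(panel); Tt <- as.integer(n_traits)
  h2 <- config$h2_total

  w <- rep(1, M)
  if (length(config$enrichment_factors)) {
    if (is.null(annotations))
      stop("enrichment_factors given but no annotations supplied", call. = FALSE)
    for (nm in names(config$enrichment_factors)) {
      f <- config$enrichment_factors[[nm]]
      if (f <= 0) stop("enrichment factor must be positive: ", nm, call. = FALSE)
      memb <- annotation_membership(annotations, panel$snps$id)[, nm]
      w <- w + (f - 1) * memb
    }
  }

  beta <- matrix(stats::rnorm(M * Tt), M, Tt)
  if (Tt > 1 && effect_cor != 0) {
    Sg <- matrix(effect_cor, Tt, Tt); diag(Sg) <- 1
    beta <- beta %*% chol(Sg)
  }
  # constant effect variance per *standardized* genotype (the usual polygenic
  # architecture): dosage-scale variance is w_j / Var(dosage_j)
  sdx <- col_moments(panel$dosages)$sd
  sdx[sdx < 1e-8] <- Inf
  beta <- beta * (sqrt(w) / sdx)

  if (h2 == 0) beta[] <- 0
  g <- cpp_genetic_values(panel$dosages, beta)
  g <- sweep(g, 2, colMeans(g))
  for (t in seq_len(Tt)) {
    if (h2 > 0) {
      vg <- stats::var(g[, t]) * (N - 1) / N
      sc <- sqrt(h2 / vg)
      g[, t] <- g[, t] * sc
      beta[, t] <- beta[, t] * sc
    }
  }

  covs <- matrix(1, N, 1)
  colnames(covs) <- "intercept"
  if (n_covariates > 0) {
    Z <- matrix(stats::rnorm(N * n_covariates), N, n_covariates)
    colnames(Z) <- paste0("cov", seq_len(n_covariates))
    covs <- cbind(covs, Z)
  }

  y <- g + matrix(stats::rnorm(N * Tt, sd = sqrt(1 - h2)), N, Tt)
  if (n_covariates > 0)
    y <- y + (covs[, -1, drop = FALSE] %*% matrix(0.1, n_covariates, Tt))
  if (!is.null(panel$subpop) && config$confound_strength > 0) {
    cc <- 2 * sqrt(config$confound_strength)   # subpop coded +/- 1/2
    y <- y + cc * (panel$subpop - 0.5)
  }

  trait_names <- paste0("trait", seq_len(Tt))
  colnames(y) <- trait_names
  structure(list(values = y, trait_names = trait_names, covariates = covs,
                 true_betas = beta),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("Phenotype matrix: %d individuals x %d traits (%d covariates)\n",
              nrow(x$values), ncol(x$values), ncol(x$covariates)))
  invisible(x)
}

#' Simulate singleton-density scores per SNP
#'
#' Under the selection null (`sds_selection_rho = 0`) SDS values are standard
#' normal and independent of effects. Under selection, the trait-increasing
#' orientation of the SDS (tSDS) is constructed to have (Pearson, hence
#' approximately rank) correlation `sds_selection_rho` with the normal scores
#' of the noise-free *marginal* association strength — the LD-convolved
#' standardized effect — since selection acts on haplotypes and the singleton
#' signal is locally smooth like the association signal. The stored SDS is
#' reported with respect to the derived allele, which in synthetic panels is
#' the effect allele.
#'
#' With `ancestry_loading > 0` (requires a stratified panel) the SDS gains a
#' component proportional to the standardized derived-allele frequency
#' difference between the two subpopulations, emulating the documented
#' susceptibility of SDS to residual population stratification.
#'
#' @param panel A `genotype_panel`.
#' @param true_betas Numeric vector of per-SNP true effects (one trait).
#' @param config A [sim_config()]; consumes `sds_selection_rho`.
#' @param dropout Fraction of SNPs lacking an SDS value; exactly
#'   `ceiling((1 - dropout) * M)` SNPs are retained.
#' @param ancestry_loading Weight in `[0, 1)` of the allele-frequency-divergence
#'   component.
#' @return An `sds_table` data frame: id, chrom, pos, derived_allele, sds.
#' @export
simulate_sds <- function(panel, true_betas, config, dropout = 0,
                         ancestry_loading = 0) {
  validate_sim_config(config)
  if (abs(config$sds_selection_rho) > 1)
    stop("sds_selection_rho must lie in [-1, 1]", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  M <- n_snps(panel)
  stopifnot(length(true_betas) == M)
  set.seed(config$seed + 2L)

  rho <- config$sds_selection_rho
  base <- stats::rnorm(M)
  if (rho != 0) {
    # Couple the trait-increasing SDS to the *marginal* (LD-convolved)
    # standardized effect: selection acts on haplotypes, so the singleton
    # signal is locally smooth, like the association signal itself.
    bm <- marginal_effects(panel, true_betas)
    u <- stats::qnorm(rank(abs(bm), ties.method = "average") / (M + 1))
    tsds <- rho * u + sqrt(1 - rho^2) * base
    sgn <- ifelse(bm >= 0, 1, -1)
  } else {
    tsds <- base
    sgn <- ifelse(true_betas >= 0, 1, -1)
  }
  sds <- tsds * sgn  # derived allele == effect allele in synthetic panels

  if (ancestry_loading != 0) {
    if (is.null(panel$subpop))
      stop("ancestry_loading requires a stratified panel", call. = FALSE)
    if (abs(ancestry_loading) >= 1)
      stop("ancestry_loading must lie in (-1, 1)", call. = FALSE)
    f0 <- colMeans(panel$dosages[panel$subpop == 0L, , drop = FALSE]) / 2
    f1 <- colMeans(panel$dosages[panel$subpop == 1L, , drop = FALSE]) / 2
    zd <- as.numeric(scale(f0 - f1))
    sds <- sqrt(1 - ancestry_loading^2) * sds + ancestry_loading * zd
  }

  out <- data.frame(
    id = panel$snps$id,
    chrom = panel$snps$chrom,
    pos = panel$snps$pos,
    derived_allele = panel$snps$allele_effect,
    sds = sds,
    stringsAsFactors = FALSE
  )
  keep_n <- as.integer(ceiling((1 - dropout) * M))
  if (keep_n < M)
    out <- out[sort(sample.int(M, keep_n)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sds_table", "data.frame")
  out
}

#' Ancestry principal-component SNP loadings of a panel
#'
#' Computes the top-k right singular vectors of the column-centered dosage
#' matrix via the individual-by-individual Gram matrix, the cohort-level
#' meaning of "ancestry PCs". Loadings are unit-norm columns aligned to the
#' panel's SNP order.
#'
#' @param panel A `genotype_panel`.
#' @param k Number of components (the replication analysis convention is 20).
#' @return M x k numeric matrix, rownames = SNP ids, columns `PC1..PCk`.
#' @export
panel_pc_loadings <- function(panel, k = 20) {
  N <- n_individuals(panel); M <- n_snps(panel)
  k <- min(k, N - 1L, M)
  mu <- colMeans(panel$dosages)
  Gc <- sweep(panel$dosages, 2, mu)
  S <- tcrossprod(Gc)
  eg <- eigen(S, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  V <- crossprod(Gc, U)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  rownames(V) <- panel$snps$id
  colnames(V) <- paste0("PC", seq_len(k))
  V
}

#' Plant synthetic interval annotations on a simulated panel
#'
#' For each named coverage fraction, places `n_intervals` non-overlapping
#' intervals (one per equal genome segment, at a seeded random offset) whose
#' SNP coverage totals the requested fraction. Useful for planting enriched
#' categories with spatially contiguous structure, mirroring how real
#' annotations (enhancer sets, deserts) occupy intervals rather than scattered
#' SNPs.
#'
#' @param panel A `genotype_panel`.
#' @param coverage Named numeric vector of SNP-coverage fractions per category.
#' @param n_intervals Intervals per category.
#' @param seed Integer seed for interval placement.
#' @return An `annotation_set` resolved against the panel SNPs.
#' @export
synthetic_annotations <- function(panel, coverage, n_intervals = 20, seed = 1L) {
  stopifnot(length(coverage) >= 1, !is.null(names(coverage)))
  M <- n_snps(panel)
  set.seed(seed)
  cats <- list()
  for (nm in names(coverage)) {
    len <- max(1L, round(coverage[[nm]] * M / n_intervals))
    seg <- floor(M / n_intervals)
    if (len >= seg) stop("coverage too high for n_intervals", call. = FALSE)
    starts <- integer(n_intervals)
    for (i in seq_len(n_intervals))
      starts[i] <- (i - 1L) * seg + sample.int(seg - len + 1L, 1)
    # SNP index range [a, a+len-1] -> 0-based half-open bp interval
    ivs <- data.frame(
      chrom = "1",
      start = (starts - 1L) * 1000L,
      end = (starts + len - 1L) * 1000L
    )
    cats[[nm]] <- list(intervals = ivs)
  }
  annotation_set(cats, reference = panel$snps)
}
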