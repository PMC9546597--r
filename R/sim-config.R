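#' Simulation configuration for synthetic cohorts
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort and panel
#' dimensions, LD-block structure, allele-frequency range, trait architecture
#' (total SNP heritability and per-category effect-variance enrichment), the
#' strength of two-subpopulation stratification, the coupling between
#' singleton-density scores and trait-increasing alleles, and the seed.
#'
#' @param n_individuals Number of individuals (rows of the dosage matrix).
#' @param n_snps Number of SNPs (columns). SNPs are placed on one synthetic
#'   chromosome at fixed 1 kb spacing.
#' @param block_size SNPs per LD block; the last block is truncated when
#'   `block_size` does not divide `n_snps`.
#' @param within_block_r Target mean pairwise dosage correlation within a
#'   block, in `[0, 1)`. The latent-Gaussian threshold construction is
#'   calibrated so the *dosage* correlation (not the latent one) hits this.
#' @param maf_range Length-2 ordered vector of minor allele frequencies in
#'   `(0, 0.5]`; per-SNP frequencies are drawn uniformly on this range.
#' @param h2_total Narrow-sense SNP heritability targeted by
#'   [simulate_phenotypes()], in `[0, 1]`. Default 0.4, the magnitude typical
#'   of total cortical surface area.
#' @param enrichment_factors Named list/vector of positive per-SNP
#'   effect-variance ratios (annotation members vs background); see
#'   [factor_for_enrichment()] for conversion from a target heritability
#'   enrichment.
#' @param confound_strength Non-negative scalar governing two-subpopulation
#'   stratification: used both as the Fst-like allele-frequency divergence
#'   (Balding–Nichols) and as the fraction of phenotypic variance explained by
#'   subpopulation membership. 0 disables stratification.
#' @param sds_selection_rho Target rank correlation between trait-increasing
#'   SDS and the (noise-free) association strength, in `[-1, 1]`. 0 gives the
#'   selection-null.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 100, n_snps = 50, block_size = 10, seed = 1)
#' @export
sim_config <- function(n_individuals,
                       n_snps,
                       block_size = 25,
                       within_block_r = 0.5,
                       maf_range = c(0.05, 0.5),
                       h2_total = 0.4,
                       enrichment_factors = list(),
                       confound_strength = 0,
                       sds_selection_rho = 0,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    block_size = as.integer(block_size),
    within_block_r = within_block_r,
    maf_range = as.numeric(maf_range),
    h2_total = h2_total,
    enrichment_factors = as.list(enrichment_factors),
    confound_strength = confound_strength,
    sds_selection_rho = sds_selection_rho,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 2 || cfg$n_snps < 1)
    stop("sim_config: non-positive or degenerate dimensions", call. = FALSE)
  if (cfg$block_size < 1)
    stop("sim_config: block_size must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$within_block_r) || cfg$within_block_r < 0 || cfg$within_block_r >= 1)
    stop("sim_config: within_block_r must lie in [0, 1)", call. = FALSE)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("sim_config: maf_range must be ordered (low, high)", call. = FALSE)
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("sim_config: maf_range must lie in (0, 0.5]", call. = FALSE)
  if (cfg$h2_total < 0 || cfg$h2_total > 1)
    stop("sim_config: h2_total must lie in [0, 1]", call. = FALSE)
  if (length(cfg$enrichment_factors) &&
      (is.null(names(cfg$enrichment_factors)) ||
       any(!nzchar(names(cfg$enrichment_factors)))))
    stop("sim_config: enrichment_factors must be named", call. = FALSE)
  for (f in cfg$enrichment_factors)
    if (!is.numeric(f) || f <= 0)
      stop("sim_config: enrichment factors must be positive", call. = FALSE)
  if (cfg$confound_strength < 0)
    stop("sim_config: confound_strength must be non-negative", call. = FALSE)
  if (abs(cfg$sds_selection_rho) > 1)
    stop("sim_config: sds_selection_rho must lie in [-1, 1]", call. = FALSE)
  if (abs(cfg$seed) >= 2^31 - 10)
    stop("sim_config: seed out of 32-bit integer range", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d   SNPs: %d   block size: %d (r = %.2f)\n",
              x$n_individuals, x$n_snps, x$block_size, x$within_block_r))
  cat(sprintf("  MAF range: [%.3f, %.3f]   h2: %.2f   confounding: %.3f   SDS rho: %.2f\n",
              x$maf_range[1], x$maf_range[2], x$h2_total,
              x$confound_strength, x$sds_selection_rho))
  if (length(x$enrichment_factors))
    cat("  enrichment factors:",
        paste(sprintf("%s=%.3g", names(x$enrichment_factors),
                      unlist(x$enrichment_factors)), collapse = ", "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Effect-variance ratio achieving a target heritability enrichment
#'
#' Heritability enrichment of a category is (share of h2)/(share of SNPs).
#' With a single category covering a fraction `p` of SNPs whose per-SNP effect
#' variance is `f` times the background, the enrichment is
#' `f / (p f + 1 - p)`.  This helper inverts that relation so a simulation can
#' plant an exact target enrichment `E`:
#' `f = E (1 - p) / (1 - E p)`, requiring `E p < 1`.
#'
#' @param enrichment Target enrichment `E` (> 0).
#' @param prop_snps Fraction of SNPs in the category, in `(0, 1)`.
#' @return The in/out per-SNP effect-variance ratio `f`.
#' @examples
#' factor_for_enrichment(10, 0.05)  # 19: plants a true enrichment of 10
#' @export
factor_for_enrichment <- function(enrichment, prop_snps) {
  stopifnot(enrichment > 0, prop_snps > 0, prop_snps < 1)
  if (enrichment * prop_snps >= 1)
    stop("target enrichment unattainable: E * prop_snps must be < 1", call. = FALSE)
  enrichment * (1 - prop_snps) / (1 - enrichment * prop_snps)
}
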