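---
title: "Partitioned heritability and polygenic selection over evolutionary genome annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned heritability and polygenic selection over evolutionary genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoanno)
```

## The analysis in one paragraph

Quantitative brain-structure traits — regional cortical surface areas,
fractional anisotropy of white-matter tracts — are heritable, and the common
variants behind them can be localized relative to genomic regions of
evolutionary interest: human-gained enhancers (HGEs) active in fetal cortex,
Neanderthal-introgressed alleles, and archaic deserts. `evoanno` implements
the full analysis chain needed to ask whether such regions carry more (or
less) than their share of SNP heritability, and whether trait-associated
alleles show signs of recent polygenic selection: variant QC and additive
per-SNP association scans; ancestry-PC regression of effect sizes;
partitioned LD-score regression with block-jackknife enrichment inference;
bivariate LD-score regression for genetic correlations; the trait-increasing
singleton-density-score (tSDS) test; an effective-number-of-traits FDR
correction; annotation curation; and LD clumping with interval overlap. A
seeded synthetic-cohort generator with known ground truth makes every stage
testable without any external data.

## The estimators

### Partitioned LD-score regression

For SNP $j$ and annotation category $C$, the partitioned LD score is

$$\ell(j, C) \;=\; \sum_{k \in C,\; |pos_k - pos_j| \le w} \tilde r^2_{jk},
\qquad
\tilde r^2 = r^2 - \frac{1 - r^2}{n_{\mathrm{ref}} - 2},$$

where $r$ is the dosage correlation in the reference cohort and the second
term removes the finite-sample upward bias of $r^2$ (the self-pair $r^2 = 1$
is bias-free). Under a polygenic model in which the effect variance of a
standardized genotype is $\tau_C$ extra for every category containing it,

$$\mathbb E[\chi^2_j] \;=\; N \sum_C \tau_C\, \ell(j, C) \;+\; 1,$$

and confounding such as population stratification lifts the intercept above
1 roughly uniformly in $\ell$. `fit_partitioned_h2()` regresses GWAS
$\chi^2$ on $\{N\,\ell(j,C)/M\}_C$ with a free intercept by weighted least
squares. Categories may overlap; heritability attribution uses
$h^2(C) = \sum_{j \in C} \sum_{C' \ni j} \tau_{C'}$, so
$h^2(\mathrm{base}) = h^2_{\mathrm{total}}$ exactly and the base (all-SNPs)
category has enrichment exactly 1 with zero SE by construction. Enrichment
is $(h^2(C)/h^2)/(M_C/M)$; its standard error comes from a delete-one-block
jackknife over contiguous equal-size SNP blocks (default 200), and the
enrichment p-value is the two-sided normal p of the jackknife t-statistic of
$\mathrm{prop}_{h^2} - \mathrm{prop}_{\mathrm{SNPs}}$ — the difference, not
the ratio, because the difference is the quantity whose null value is exact
under no enrichment. Estimates below 1 with a significant p are labelled
depletions. A bivariate variant regresses $z_1 z_2$ on
$\sqrt{N_1 N_2}\,\ell/M$ to estimate genetic covariance, and
$r_g = \mathrm{gencov}/\sqrt{h^2_1 h^2_2}$; all three regressions share
weights and exclusion rules, which makes the self-correlation of a trait
exactly 1 — a useful internal identity.

Numerical choices, all configurable:

* **Window** $w$: 1 Mb physical by default. The canonical choice is 1 cM,
  but a synthetic genome has no genetic map. Because the generator's LD
  blocks span at most `block_size` kb, the package's own experiments use
  30–50 kb windows; beyond the block span additional pairs contribute only
  mean-zero bias-corrected noise, and we verified the fits are unchanged
  between 30 kb and 1 Mb windows on block-structured panels.
* **Weights**: $1/(\ell_j (1 + N \bar h^2 \ell_j / M)^2)$, with $\bar h^2$
  from a preliminary unweighted pass; two-step, not iterated. This is the
  usual compromise between heteroskedasticity and double-counting.
* **Outliers**: SNPs with $\chi^2 > \max(80,\, 0.001N)$ are excluded from
  the regression (never from $M$) to limit leverage.
* **Collinearity**: a condition number above $10^{12}$ triggers a warning
  and a pseudo-inverse fit.

### The tSDS polygenic-selection test

Singleton density scores measure recent allele-frequency change. After an
inner join of summary statistics with the SDS table (SNPs without SDS are
dropped; mismatching alleles are reconciled directly or by strand
complement, with the SDS sign flipped when the derived allele matches the
non-effect allele; irreconcilable pairs are dropped with a logged count),
both quantities are oriented to the trait-increasing allele:
$\mathrm{tSDS} = \mathrm{SDS} \cdot \mathrm{sign}(\beta)$ against $|Z|$.
`tsds_test()` computes their Spearman correlation with a delete-one-block
jackknife SE over 100 contiguous genomic blocks and a two-sided normal
p-value. Ties take average ranks. The test's vulnerability to residual
stratification is real and reproduced by the generator (below); the
recommended guard is `ancestry_regress()`, which replaces betas by their
residuals on the top ancestry-PC SNP loadings (intercept included), keeping
SE and N unchanged and recomputing Z — an idempotent operation.

### Effective number of traits and FDR

Brain-structure trait families are strongly correlated. `veff_li()` applies
the eigenvalue-spectrum rule to a trait correlation matrix:
$V_{\mathrm{eff}} = \sum_i \big[\mathbb 1(|\lambda_i| \ge 1) + (|\lambda_i| -
\lfloor |\lambda_i| \rfloor)\big]$. The floor uses a $10^{-9}$ tolerance so
an eigenvalue numerically just below an integer does not contribute a
spurious fractional part near 1. The intended input is the genetic
correlation matrix from `fit_rg()` across trait pairs; since noisy pairwise
fits need not be positive semi-definite, `repair_correlation()` clips
negative eigenvalues and rescales the diagonal first. `bh_fdr()` is a
Benjamini–Hochberg step-up in which the denominator $m$ is replaced by
$\lceil V_{\mathrm{eff}} \rceil$ when that is smaller than the number of
p-values — our operationalization of correcting "for $k$ independent
traits"; whether the original analyses instead selected a trait subset is
not recoverable, and the choice is conservative in the regimes exercised
here. The selection-test arm deliberately uses plain BH across traits (no
effective-count reduction), the conservative convention for that analysis.

### Annotation curation and loci

Interval annotations are BED-style 0-based half-open; SNP positions are
1-based; a SNP at position $p$ is inside $[s, e)$ iff $s \le p-1 < e$. The
curation operations mirror how evolutionary annotations are actually
assembled: `merge_intervals()` pools developmental-stage-specific enhancer
maps into one category; `ld_expand()` grows a SNP list by LD, with
$r^2 \ge 1$ (numerical tolerance) for perfect proxies and strict
$r^2 > t$ otherwise — both uses of one code path; `refine_deserts()`
removes introgressed SNPs inside archaic deserts together with their
$r^2 > 0.6$ haplotype partners; and `snp_coverage()` enforces the rule that
an annotation must cover at least 1% (inclusive) of the QC-passed reference
SNPs to be analyzed. `clump_loci()` groups genome-wide significant SNPs
($p < 5\times10^{-8}$) greedily around the most significant lead, admitting
members with $r^2 > 0.6$ within the window, merging loci that share
members; ties in p break by genomic position so the result is invariant to
input row order. Locus spans are the min/max member positions with no
padding. `overlap_annotations()` intersects locus spans with interval sets
(HARs, AMH-derived DMRs) under the same half-open convention.

## What the synthetic cohorts emulate

`simulate_panel()` draws one latent Gaussian per genotype and applies two
cut points, giving exact binomial(2, p) margins under Hardy–Weinberg and a
controllable within-block exchangeable correlation. Because thresholding
attenuates correlation, the latent level is calibrated numerically (a
tabulated curve of mean dosage correlation versus latent correlation,
inverted by monotone interpolation) so that the *dosage* correlation hits
the configured target; the calibration integrates the bivariate normal
orthant probability by one-dimensional quadrature and is checked against a
Monte-Carlo oracle in the tests. Key design choices:

* **One synthetic chromosome, SNPs at fixed 1 kb spacing** — keeps all
  window and interval logic exercised without a genetic map.
* **Heterogeneous LD**: per-block target correlations are drawn uniformly
  around `within_block_r` with a symmetric spread (up to ±0.3, shrunk near
  the attainable boundary), so the mean is exact. Real genomes mix tight
  and loose LD; a genome with identical blocks leaves the $\chi^2$-on-$\ell$
  regression with almost no leverage and the slope/intercept split poorly
  identified — heterogeneity is what makes the regression estimable, as it
  is in real data. The maximum attainable dosage correlation for the
  default MAF range (0.05–0.5) is about 0.78; requesting more errors out.
* **Effect sizes on the standardized-genotype scale**: per-SNP effect
  variance is constant per standardized genotype (the usual polygenic
  architecture and exactly the model the regression assumes), multiplied by
  the per-category `enrichment_factors` for members, composing additively
  over overlapping categories. The genetic component is rescaled so realized
  narrow-sense $h^2$ equals `h2_total` exactly in-sample; the default 0.4
  matches the magnitude reported for total cortical surface area.
* **`enrichment_factors` are in/out variance ratios**, not heritability
  enrichments. With a category covering a fraction $p$ of SNPs, a ratio $f$
  yields true enrichment $f/(pf + 1 - p)$; `factor_for_enrichment(E, p)`
  inverts this, so planting a *true enrichment* of 10 on a 5% category uses
  a ratio of 19. The package's recovery experiments plant enrichment 10
  this way.
* **Stratification**: `confound_strength` doubles as the Balding–Nichols
  Fst between two equal subpopulations and as the fraction of phenotypic
  variance explained by subpopulation membership. One knob produces both
  the allele-frequency divergence and the phenotype shift that together
  create spurious associations.
* **SDS**: under the null, standard normal and independent of everything.
  Under selection, tSDS is coupled (at Pearson correlation
  `sds_selection_rho`) to the normal scores of the noise-free *marginal*
  standardized effect — the LD-convolved effect, not the causal one —
  because selection acts on haplotypes and the singleton signal is locally
  smooth exactly like the association signal. Coupling to the causal effect
  instead would make the test essentially powerless at realistic LD, since
  $|Z|$ reflects the marginal effect. With `ancestry_loading > 0` the SDS
  additionally picks up the standardized derived-allele frequency
  difference between subpopulations, reproducing the documented
  susceptibility of SDS to residual stratification.
* **INFO scores** are uniform(0.4, 1), so the INFO ≥ 0.7 filter removes a
  substantial fraction of SNPs and the QC stage has real work to do.
* The derived allele is identified with the effect allele, which fixes the
  tSDS alignment convention deterministically in synthetic data.

What the generator does **not** emulate: realistic site-frequency spectra,
recombination-map structure, mutation processes, relatedness and cryptic
kinship, imputation error correlated with MAF, or annotation boundaries
correlated with recombination. Passing tests therefore establish the
correctness and calibration of the estimators under the stated model, not
robustness to every property of real cohort data.

## Experiment sizes

The packaged experiments (test suite and `scripts/acceptance.R`) use:
enrichment recovery at $N = 5000$, $M = 20000$, $h^2 = 0.5$, a 5% category
at true enrichment 10, 200 jackknife blocks; null calibration at $N = 1000$,
$M = 4000$ over 100 replicates with 80 jackknife blocks — jackknife blocks
must span several LD blocks to be approximately exchangeable units, so at
small $M$ the block count is reduced rather than letting blocks shrink
below the LD span; stratification behavior at $N = 1000$,
$M = 5000$, Fst 0.02; tSDS size at $N = 500$, $M = 10000$ (200 null seeds)
and power at $N = 2000$, rank correlation 0.1; the end-to-end pipeline at
its default $N = 1000$, $M = 5000$ with two shared-architecture traits.
These sizes were chosen as the smallest at which each property is
identified with comfortable margin.

## A minimal session

```{r example, eval = FALSE}
f <- factor_for_enrichment(10, 0.05)
cfg <- sim_config(n_individuals = 2000, n_snps = 8000,
                  h2_total = 0.4, enrichment_factors = list(HGE_like = f),
                  seed = 1)
report <- run_pipeline(pipeline_config(sim = cfg, out_dir = "run1"))
print(report)
summary(report$h2$trait1)
```

## Known limitations

* The LD reference is the GWAS cohort itself; external-reference workflows
  would need their own panel object (the data structures allow it, the
  pipeline does not orchestrate it).
* No liability-scale transformation, continuous-valued annotations, or
  sample-overlap-aware genetic-correlation corrections beyond the free
  cross-trait intercept.
* `veff_li()` follows the eigenvalue rule as published; its discontinuity
  at integer eigenvalues is inherent to the rule (the tolerance only guards
  numerical noise).
* At very small panels ($M \lesssim 2000$ regression SNPs) the
  slope/intercept split of the LD-score regression is weakly identified and
  enrichment ratios can be unstable when $\hat h^2 \approx 0$; the pipeline
  records an undefined genetic correlation as 0 rather than aborting.
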