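# evoanno

Evolutionary genome annotations and the genetics of brain structure.

Large neuroimaging-genetics cohorts make it possible to ask which parts of
our evolutionary history still shape variation in brain anatomy: do common
variants inside human-gained enhancers (HGEs) active in fetal cortex,
Neanderthal-introgressed alleles, or archaic deserts contribute more — or
less — than their share of SNP heritability for cortical surface area and
white-matter microstructure? And do trait-associated alleles show signatures
of recent polygenic selection? `evoanno` implements that analysis chain for
statistical geneticists and evolutionary neuroscientists, together with a
seeded synthetic-cohort generator with known ground truth, so every stage is
testable end to end without access to any biobank.

## What is inside

| Stage | Functions |
|---|---|
| Synthetic cohorts (LD blocks, stratification, annotation-stratified polygenic traits, SDS) | `sim_config()`, `simulate_panel()`, `simulate_phenotypes()`, `simulate_sds()`, `synthetic_annotations()` |
| Variant QC + additive GWAS | `qc_variants()`, `run_gwas()`, `write_sumstats()` |
| Ancestry regression | `panel_pc_loadings()`, `pc_beta_jackknife()`, `ancestry_regress()` |
| Partitioned LD-score regression | `compute_ld_scores()`, `fit_partitioned_h2()`, `fit_rg()` |
| Polygenic selection | `align_tsds()`, `tsds_test()` |
| Multiple testing | `veff_li()`, `repair_correlation()`, `bh_fdr()` |
| Annotation curation | `merge_intervals()`, `ld_expand()`, `refine_deserts()`, `snp_coverage()` |
| Loci | `clump_loci()`, `overlap_annotations()`, `generations_to_mya()` |
| Orchestration | `pipeline_config()`, `run_pipeline()` (CLI wrapper in `inst/scripts/run_pipeline.R`) |

## The statistics at the core

Partitioned LD-score regression: with partitioned scores
`l(j,C) = sum over k in C within a window of adj-r2(j,k)`,
`adj-r2 = r2 − (1−r2)/(n_ref−2)`, the per-SNP association chi-square obeys

    E[chi2_j] = N * sum_C tau_C * l(j,C) + intercept,

fit by two-step weighted least squares with a free intercept (an intercept
above 1 flags stratification). Heritability attribution is overlap-aware,
`h2(C) = sum_{j in C} sum_{C' ∋ j} tau_{C'}`; enrichment is the category's
share of h² over its share of SNPs, with delete-one-block jackknife SEs and
a p-value from the jackknife t of `prop_h2 − prop_snps`. The bivariate
variant regresses `z1·z2` on `sqrt(N1·N2)·l/M` for genetic correlations.
The tSDS test orients singleton-density scores and Z-scores to the
trait-increasing allele and computes a 100-block jackknife Spearman
correlation. The effective number of independent traits is the eigenvalue
rule `sum_i [1(|λ_i| ≥ 1) + (|λ_i| − floor|λ_i|)]`, feeding a
Benjamini–Hochberg step-up whose denominator is the effective count.
Details and design rationale: `vignettes/evolutionary-annotations.Rmd`.

## Worked example

Simulate a cohort of 2,000 individuals and 8,000 SNPs in which a planted
"HGE-like" annotation covering 5% of SNPs carries a true per-SNP
heritability enrichment of 10, then run the full pipeline:

```r
library(evoanno)
f <- factor_for_enrichment(10, 0.05)          # in/out variance ratio 19
cfg <- sim_config(2000, 8000, h2_total = 0.4,
                  enrichment_factors = list(HGE_like = f), seed = 42)
report <- run_pipeline(pipeline_config(sim = cfg, out_dir = tempfile()))
print(report$h2$trait1)
```

```
Partitioned SNP-heritability (stratified LD-score regression)
  h2 = 0.4997 (SE 0.1422)   intercept = 0.7653 (SE 0.2170)   mean chi2 = 1.854
  3977 SNPs in regression of 3977; 200 jackknife blocks
     category prop_snps prop_h2 enrichment se_enrichment p_enrichment      label
         base    1.0000  1.0000       1.00         0.000           NA
     HGE_like    0.0533  0.5001       9.38         2.438     0.000586 enrichment
 functional_A    0.1011  0.0485       0.48         0.454     0.252561
 functional_B    0.1536  0.1855       1.21         0.431     0.629670
```

Roughly half the simulated SNPs survive the imputation-quality filter
(INFO is drawn uniform(0.4, 1)), which is why 3,977 SNPs remain. The
planted category is recovered at enrichment 9.38 ± 2.44 (truth 10) and is
the only one flagged significant; the two decoy "functional" categories
sit near 1. The category carries half the heritability
(`prop_h2` 0.50) on 5.3% of SNPs — that ratio is the enrichment.
`report$summary` carries the FDR-corrected verdicts across traits,
`report$sds` the selection test (null here, as simulated), and
`report$loci` the clumped genome-wide significant loci.

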