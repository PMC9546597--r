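Package: evoanno
Title: Evolutionary Genome Annotations and the Genetics of Brain Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, association scanning and evolutionary-annotation analysis of
    quantitative traits such as cortical surface area and white-matter microstructure.
    Provides seeded synthetic cohorts with linkage-disequilibrium block structure and
    annotation-stratified polygenic architectures; variant quality control and additive
    per-SNP association scans; ancestry-principal-component regression of summary
    statistics; partitioned LD-score regression with block-jackknife enrichment and
    depletion inference; bivariate LD-score regression for genetic correlations; the
    trait-increasing singleton-density-score (tSDS) polygenic selection test; effective
    number of independent traits by eigenvalue decomposition with FDR control; curation
    of interval- and SNP-list-based genome annotations; and LD clumping of significant
    loci with interval-overlap reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
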