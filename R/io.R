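#' Write a genotype panel to plain-text files
#'
#' Produces `<prefix>_dosages.tsv` (individuals x SNPs, header = SNP ids)
#' and `<prefix>_snps.tsv` (ID, CHR, BP, A1, A2, MAF, INFO, with A1 the
#' effect allele), plus `<prefix>_subpop.tsv` when the panel is stratified.
#'
#' @param panel A `genotype_panel`.
#' @param prefix Path prefix.
#' @return The prefix, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  utils::write.table(panel$dosages, paste0(prefix, "_dosages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(ID = panel$snps$id, CHR = panel$snps$chrom,
                     BP = panel$snps$pos, A1 = panel$snps$allele_effect,
                     A2 = panel$snps$allele_other, MAF = panel$snps$maf,
                     INFO = panel$snps$info)
  utils::write.table(meta, paste0(prefix, "_snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(panel$subpop))
    utils::write.table(data.frame(subpop = panel$subpop),
                       paste0(prefix, "_subpop.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write phenotypes and covariates to TSV
#'
#' @param pheno A `phenotype_matrix`.
#' @param prefix Path prefix; writes `<prefix>_phenotypes.tsv` and
#'   `<prefix>_covariates.tsv`.
#' @export
write_phenotypes <- function(pheno, prefix) {
  utils::write.table(pheno$values, paste0(prefix, "_phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pheno$covariates, paste0(prefix, "_covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write / read ancestry-PC SNP loadings (SNP, PC1..PCK)
#'
#' @param loadings SNP x PC matrix with rownames = SNP ids.
#' @param path File path.
#' @export
write_loadings <- function(loadings, path) {
  df <- data.frame(SNP = rownames(loadings), as.data.frame(loadings))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loadings
#' @export
read_loadings <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$SNP
  m
}
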