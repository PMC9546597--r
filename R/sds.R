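complement_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

#' Align singleton-density scores to trait-increasing alleles
#'
#' Inner-joins summary statistics with an SDS table by SNP id (SNPs lacking
#' an SDS value are removed), reconciles alleles, and orients both
#' quantities to the trait-increasing allele. Where the summary-statistic
#' effect allele differs from the SDS derived allele (directly or via strand
#' complement), the SDS sign is flipped; allele pairs that are neither a
#' match, a swap, nor a complement thereof are dropped with a logged count.
#' `tsds = sds * sign(beta)` so positive tSDS marks selection favoring the
#' trait-increasing allele, and the companion `z_inc = |z|` is the Z-score in
#' the same orientation. Output is sorted by genomic position.
#'
#' @param stats A `sumstats` data frame.
#' @param sds An `sds_table` (id, chrom, pos, derived_allele, sds).
#' @return A data frame (id, chrom, pos, tsds, z_inc, beta, sds) of class
#'   `tsds_table`, sorted by position, with attribute `n_dropped_alleles`.
#' @export
align_tsds <- function(stats, sds) {
  stopifnot(all(c("id", "derived_allele", "sds") %in% names(sds)))
  idx <- match(stats$id, sds$id)
  keep <- which(!is.na(idx))
  st <- stats[keep, , drop = FALSE]
  sd_ <- sds[idx[keep], , drop = FALSE]

  eff <- toupper(st$allele_effect); oth <- toupper(st$allele_other)
  der <- toupper(sd_$derived_allele)
  aligned <- der == eff | der == complement_allele(eff)
  swapped <- der == oth | der == complement_allele(oth)
  ambiguous <- aligned & swapped        # palindromic pair: keep direct match
  swapped[ambiguous] <- FALSE
  bad <- !aligned & !swapped
  n_drop <- sum(bad)
  if (n_drop)
    message(n_drop, " SNP(s) dropped: irreconcilable allele pairs")

  st <- st[!bad, , drop = FALSE]
  sval <- sd_$sds[!bad]
  sval[swapped[!bad]] <- -sval[swapped[!bad]]

  sgn <- ifelse(st$beta >= 0, 1, -1)
  out <- data.frame(
    id = st$id, chrom = st$chrom, pos = st$pos,
    tsds = sval * sgn,
    z_inc = abs(st$z),
    beta = st$beta,
    sds = sval,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_alleles") <- n_drop
  class(out) <- c("tsds_table", "data.frame")
  out
}

#' Block-jackknife Spearman test for recent polygenic selection
#'
#' Computes the Spearman correlation between trait-increasing SDS and
#' trait-increasing-oriented GWAS Z-scores, with a standard error from a
#' delete-one-block jackknife over contiguous genomic blocks (default 100,
#' the convention of the replication analysis) and a two-sided p-value from
#' the normal reference. Ties are resolved by average ranks.
#'
#' @param merged A `tsds_table` from [align_tsds()], rows sorted by position.
#' @param n_blocks Number of contiguous jackknife blocks (default 100).
#' @return An `sds_result`: rho, se_jack, z, p, n_snps, n_blocks.
#' @export
tsds_test <- function(merged, n_blocks = 100) {
  stopifnot(all(c("tsds", "z_inc") %in% names(merged)))
  n <- nrow(merged)
  if (n < n_blocks) stop("fewer SNPs than jackknife blocks", call. = FALSE)
  if (stats::sd(merged$tsds) == 0 || stats::sd(merged$z_inc) == 0)
    stop("degenerate input: constant tSDS or Z", call. = FALSE)
  jk <- jackknife_blocks(n, n_blocks, function(idx)
    stats::cor(merged$tsds[idx], merged$z_inc[idx], method = "spearman"))
  zz <- if (jk$se > 0) jk$estimate / jk$se else Inf * sign(jk$estimate)
  structure(list(rho = jk$estimate, se_jack = jk$se, z = zz,
                 p = 2 * stats::pnorm(-abs(zz)),
                 n_snps = n, n_blocks = n_blocks),
            class = "sds_result")
}

#' @export
print.sds_result <- function(x, ...) {
  cat(sprintf(
    "tSDS polygenic selection test: rho = %.4f (jackknife SE %.4f), z = %.2f, p = %.3g\n",
    x$rho, x$se_jack, x$z, x$p))
  cat(sprintf("  %d SNPs, %d blocks\n", x$n_snps, x$n_blocks))
  invisible(x)
}

#' Write / read an SDS table TSV (ID, CHR, POS, DA, SDS)
#' @param sds An `sds_table`.
#' @param path File path.
#' @export
write_sds <- function(sds, path) {
  utils::write.table(
    data.frame(ID = sds$id, CHR = sds$chrom, POS = sds$pos,
               DA = sds$derived_allele, SDS = sds$sds),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sds
#' @export
read_sds <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- data.frame(id = df$ID, chrom = as.character(df$CHR), pos = df$POS,
                    derived_allele = df$DA, sds = df$SDS,
                    stringsAsFactors = FALSE)
  class(out) <- c("sds_table", "data.frame")
  out
}
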