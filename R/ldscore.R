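#' Partitioned LD scores
#'
#' For every SNP j and annotation category C, computes
#' `l(j, C) = sum over k in C, |pos_k - pos_j| <= window of adj-r2(j, k)`
#' where the squared dosage correlation is bias-adjusted for the finite
#' reference sample: `adj-r2 = r2 - (1 - r2) / (n_ref - 2)`. The self-pair is
#' included when SNP j belongs to C (r2 = 1 is bias-free). An all-SNPs
#' "base" category is always present (prepended when the annotation set does
#' not define one), as required by the regression fits.
#'
#' The window is physical distance; the default 1 Mb stands in for the
#' canonical 1 cM window, which has no meaning on a synthetic genome without
#' a genetic map.
#'
#' @param panel A QC'd `genotype_panel`; its cohort is the LD reference
#'   (`n_ref = N`).
#' @param annotations Optional `annotation_set` resolved against the panel
#'   SNPs; NULL gives base-only scores (univariate regression).
#' @param window Physical window in bp (> 0).
#' @return An `ld_score_table`: list with `scores` (M x C matrix), `snps`,
#'   `membership` (M x C logical), `M_C` (category SNP counts), `n_ref`,
#'   `window`.
#' @export
compute_ld_scores <- function(panel, annotations = NULL, window = 1e6) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (window <= 0) stop("window must be positive", call. = FALSE)
  N <- n_individuals(panel); M <- n_snps(panel)
  if (N <= 2) stop("LD reference requires n_ref > 2", call. = FALSE)

  if (is.null(annotations)) {
    memb <- matrix(TRUE, M, 1, dimnames = list(panel$snps$id, "base"))
  } else {
    memb <- annotation_membership(annotations, panel$snps$id)
    if (!"base" %in% colnames(memb))
      memb <- cbind(base = rep(TRUE, M), memb)
  }
  storage.mode(memb) <- "double"

  mom <- col_moments(panel$dosages)
  # constant SNPs are zeroed: they contribute no correlation
  Gs <- cpp_standardize(panel$dosages, mom$mean, mom$sd, 1e-12)

  scores <- matrix(0, M, ncol(memb))
  pos <- panel$snps$pos
  chroms <- panel$snps$chrom
  for (ch in unique(chroms)) {
    gi <- which(chroms == ch)
    gi <- gi[order(pos[gi])]
    scores[gi, ] <- cpp_band_ldscores(Gs[, gi, drop = FALSE],
                                      as.numeric(pos[gi]), window,
                                      memb[gi, , drop = FALSE])
  }
  dimnames(scores) <- list(panel$snps$id, colnames(memb))
  structure(list(scores = scores,
                 snps = panel$snps[, c("id", "chrom", "pos")],
                 membership = memb > 0,
                 M_C = colSums(memb),
                 n_ref = N,
                 window = window),
            class = "ld_score_table")
}

#' @export
print.ld_score_table <- function(x, ...) {
  cat(sprintf("LD-score table: %d SNPs x %d categories (n_ref = %d, window = %g bp)\n",
              nrow(x$scores), ncol(x$scores), x$n_ref, x$window))
  cat(sprintf("  mean l(base) = %.2f\n", mean(x$scores[, "base"])))
  invisible(x)
}

#' Write / read an LD-score table as TSV
#'
#' Layout: CHR, SNP, BP, then one score column per category; a companion
#' `<path>.M` file holds the per-category SNP counts.
#'
#' @param ldscores An `ld_score_table`.
#' @param path Output TSV path.
#' @export
write_ld_scores <- function(ldscores, path) {
  df <- data.frame(CHR = ldscores$snps$chrom, SNP = ldscores$snps$id,
                   BP = ldscores$snps$pos)
  df <- cbind(df, as.data.frame(ldscores$scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mfile <- paste0(path, ".M")
  utils::write.table(
    data.frame(category = names(ldscores$M_C), M = as.integer(ldscores$M_C)),
    mfile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
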