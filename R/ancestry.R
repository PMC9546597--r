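# Contiguous equal-size block assignment over n items; the last block absorbs
# the remainder. Deterministic, used by every jackknife in the package.
block_assign <- function(n, n_blocks) {
  if (n_blocks < 2) stop("need at least 2 jackknife blocks", call. = FALSE)
  if (n < n_blocks) stop("fewer observations than jackknife blocks", call. = FALSE)
  size <- n %/% n_blocks
  b <- pmin(((seq_len(n) - 1L) %/% size) + 1L, n_blocks)
  b
}

# Delete-one-block jackknife of a statistic computed by `fn(keep_idx)`.
# Returns estimate (full data), jackknife SE, and the leave-one-out values.
jackknife_blocks <- function(n, n_blocks, fn) {
  blocks <- block_assign(n, n_blocks)
  est <- fn(seq_len(n))
  loo <- vapply(seq_len(n_blocks),
                function(b) fn(which(blocks != b)), numeric(1))
  B <- n_blocks
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, loo = loo, n_blocks = B)
}

#' Block-jackknife Spearman correlation between ancestry PC loadings and betas
#'
#' For each ancestry principal component, computes the Spearman correlation
#' between GWAS effect sizes and the PC's SNP loadings, with a standard error
#' from a delete-one-block jackknife over contiguous equal-size SNP blocks
#' (robust to local LD). A significant correlation indicates residual
#' population-stratification signal in the summary statistics.
#'
#' @param stats A `sumstats` data frame, SNPs sorted by genomic position.
#' @param loadings Numeric SNP x PC matrix row-aligned with `stats` (rownames
#'   = SNP ids, as from [panel_pc_loadings()]).
#' @param n_blocks Number of jackknife blocks (default 200).
#' @return A `pc_jackknife` data frame with one row per PC: estimate,
#'   se_jack, z, p, n_blocks.
#' @export
pc_beta_jackknife <- function(stats, loadings, n_blocks = 200) {
  loadings <- align_loadings(stats, loadings)
  M <- nrow(stats)
  if (is.unsorted(stats$pos[stats$chrom == stats$chrom[1]]))
    stats <- stats[order(stats$chrom, stats$pos), ]
  res <- lapply(colnames(loadings), function(pc) {
    v <- loadings[, pc]
    jk <- jackknife_blocks(M, n_blocks, function(idx)
      stats::cor(stats$beta[idx], v[idx], method = "spearman"))
    zz <- if (jk$se > 0) jk$estimate / jk$se else Inf * sign(jk$estimate)
    data.frame(pc = pc, estimate = jk$estimate, se_jack = jk$se, z = zz,
               p = 2 * stats::pnorm(-abs(zz)), n_blocks = jk$n_blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("pc_jackknife", "data.frame")
  out
}

#' @export
print.pc_jackknife <- function(x, ...) {
  cat("Ancestry PC vs GWAS beta: block-jackknife Spearman correlations\n")
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

align_loadings <- function(stats, loadings) {
  L <- as.matrix(loadings)
  if (!is.null(rownames(L))) {
    idx <- match(stats$id, rownames(L))
    if (anyNA(idx)) stop("loadings missing SNPs present in stats", call. = FALSE)
    L <- L[idx, , drop = FALSE]
  } else if (nrow(L) != nrow(stats)) {
    stop("loadings not aligned with summary statistics", call. = FALSE)
  }
  if (is.null(colnames(L))) colnames(L) <- paste0("PC", seq_len(ncol(L)))
  L
}

#' Ancestry regression of GWAS effect sizes
#'
#' Replaces each beta by the residual of the multiple regression of betas on
#' all ancestry-PC SNP loadings (with intercept), removing effect-size
#' gradients aligned with ancestry axes. Z is recomputed as residual beta
#' over the original (unchanged) standard error, so the chi-square scale is
#' preserved; N is unchanged; p-values are refreshed from the new Z. The
#' operation is idempotent and leaves betas orthogonal to the loadings.
#'
#' @param stats A `sumstats` data frame.
#' @param loadings SNP x PC loading matrix aligned (or alignable by rownames)
#'   with `stats`.
#' @return A `sumstats` data frame with attribute
#'   `ancestry_regressed = TRUE`.
#' @export
ancestry_regress <- function(stats, loadings) {
  L <- align_loadings(stats, loadings)
  if (ncol(L) >= nrow(stats))
    stop("more PCs than SNPs: ancestry regression undetermined", call. = FALSE)
  X <- cbind(1, L)
  fit <- stats::lm.fit(X, stats$beta)
  out <- stats
  out$beta <- as.numeric(fit$residuals)
  out$z <- ifelse(is.finite(out$se) & out$se > 0, out$beta / out$se, 0)
  out$chi2 <- out$z^2
  out$p <- if (max(stats$n) > 200) 2 * stats::pnorm(-abs(out$z))
           else 2 * stats::pt(-abs(out$z), max(stats$n) - ncol(X) - 1)
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  attr(out, "ancestry_regressed") <- TRUE
  out
}
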