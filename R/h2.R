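# Moore-Penrose pseudoinverse via SVD; used only when the category design is
# numerically collinear.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

solve_or_pinv <- function(A, b) {
  kap <- kappa(A, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    warning("collinear category LD scores (condition number ", format(kap),
            "); using pseudo-inverse fit", call. = FALSE)
    return(as.numeric(pinv(A) %*% b))
  }
  as.numeric(solve(A, b))
}

# Align summary statistics with an LD-score table; returns row indices into
# the table plus the subset stats, in table (genomic) order.
align_stats_ld <- function(stats, ldscores) {
  idx <- match(ldscores$snps$id, stats$id)
  keep <- which(!is.na(idx))
  if (!length(keep)) stop("no SNP overlap between stats and LD scores", call. = FALSE)
  list(tab_idx = keep, stats = stats[idx[keep], , drop = FALSE])
}

# Shared machinery: per-block weighted least-squares accumulators for
# y ~ X (X includes intercept as last column), returning full-data and
# leave-one-block-out coefficient vectors.
wls_jackknife <- function(X, y, w, n_blocks) {
  n <- nrow(X)
  blocks <- block_assign(n, n_blocks)
  p <- ncol(X)
  A <- array(0, c(p, p, n_blocks)); Bv <- matrix(0, p, n_blocks)
  for (b in seq_len(n_blocks)) {
    r <- which(blocks == b)
    Xb <- X[r, , drop = FALSE] * w[r]
    A[, , b] <- crossprod(X[r, , drop = FALSE], Xb)
    Bv[, b] <- crossprod(Xb, y[r])
  }
  At <- apply(A, c(1, 2), sum); bt <- rowSums(Bv)
  theta <- solve_or_pinv(At, bt)
  loo <- matrix(0, p, n_blocks)
  for (b in seq_len(n_blocks))
    loo[, b] <- solve_or_pinv(At - A[, , b], bt - Bv[, b])
  list(theta = theta, loo = loo, n_blocks = n_blocks)
}

jack_se <- function(v) {
  B <- length(v)
  sqrt((B - 1) / B * sum((v - mean(v))^2))
}

#' Partitioned SNP-heritability by stratified LD-score regression
#'
#' Fits the weighted least-squares regression of per-SNP association
#' chi-square on category-partitioned LD scores,
#' `E[chi2_j] = N * sum_C tau_C * l(j, C) + intercept`, with a free intercept
#' (values above 1 indicate confounding such as population stratification).
#' Coefficients are reported on the per-SNP `tau` scale. Heritability of a
#' category uses the overlap-aware accounting
#' `h2(C) = sum_{j in C} sum_{C' containing j} tau_{C'}`; its share of total
#' h2 divided by the category's share of SNPs is the enrichment. Enrichment
#' standard errors come from a delete-one-block jackknife over contiguous
#' equal-size SNP blocks, and the enrichment p-value is the two-sided normal
#' p of the jackknife t-statistic of `prop_h2 - prop_snps`. With base-only LD
#' scores the fit is the univariate regression returning total h2 and the
#' intercept.
#'
#' Regression weights are `1 / (l_base * (1 + N * h2bar * l_base / M)^2)`
#' with `h2bar` taken from a preliminary unweighted pass (two-step, not
#' iterated); SNPs with `chi2 > max(80, 0.001 N)` are excluded from the
#' regression (but not from M) to limit outlier leverage.
#'
#' @param stats A `sumstats` data frame.
#' @param ldscores An `ld_score_table` containing a base (all-SNPs) category.
#' @param n_blocks Jackknife blocks (default 200).
#' @return A `partitioned_h2` object; see [print.partitioned_h2()],
#'   `summary`, and `coef` (per-SNP tau per category).
#' @export
fit_partitioned_h2 <- function(stats, ldscores, n_blocks = 200) {
  stopifnot(inherits(ldscores, "ld_score_table"))
  if (!"base" %in% colnames(ldscores$scores))
    stop("LD-score table lacks the all-SNPs base category", call. = FALSE)
  al <- align_stats_ld(stats, ldscores)
  st <- al$stats
  sc <- ldscores$scores[al$tab_idx, , drop = FALSE]
  memb <- ldscores$membership
  M_tot <- nrow(ldscores$scores)
  M_C <- ldscores$M_C
  cats <- colnames(sc)

  chi2 <- st$z^2
  Nv <- st$n
  thr <- max(80, 0.001 * stats::median(Nv))
  ok <- chi2 <= thr & !st$missing & is.finite(chi2)
  if (sum(ok) <= length(cats) + 2)
    stop("too few SNPs retained for the regression", call. = FALSE)

  X <- sweep(sc[ok, , drop = FALSE], 1, Nv[ok] / M_tot, "*")
  X <- cbind(X, intercept = 1)
  y <- chi2[ok]

  # preliminary unweighted pass for the weight heritability
  th0 <- stats::lm.fit(X, y)$coefficients
  th0[is.na(th0)] <- 0
  h2bar <- sum(th0[cats] * M_C[cats]) / M_tot
  h2bar <- min(max(h2bar, 0), 1)

  lb <- pmax(sc[ok, "base"], 1)
  w <- 1 / (lb * (1 + Nv[ok] * h2bar * lb / M_tot)^2)

  fit <- wls_jackknife(X, y, w, n_blocks)

  # overlap counts O[C, C'] = |C intersect C'|
  O <- crossprod(memb * 1)
  derive <- function(theta) {
    tc <- stats::setNames(theta[seq_along(cats)], cats)
    h2_C <- as.numeric(O %*% tc) / M_tot
    names(h2_C) <- cats
    h2_tot <- h2_C["base"]
    prop_h2 <- h2_C / h2_tot
    prop_snps <- M_C / M_tot
    list(tau = tc / M_tot, h2_C = h2_C, h2_total = as.numeric(h2_tot),
         prop_h2 = prop_h2, prop_snps = prop_snps,
         enrichment = prop_h2 / prop_snps,
         d = prop_h2 - prop_snps,
         intercept = theta[length(theta)])
  }

  full <- derive(fit$theta)
  loo <- apply(fit$loo, 2, derive)
  se_of <- function(get) vapply(cats, function(cc)
    jack_se(vapply(loo, function(l) get(l)[[cc]], numeric(1))), numeric(1))
  se_enr <- se_of(function(l) l$enrichment)
  se_d <- se_of(function(l) l$d)
  se_tau <- vapply(cats, function(cc)
    jack_se(vapply(loo, function(l) l$tau[[cc]], numeric(1))), numeric(1))
  se_h2 <- jack_se(vapply(loo, function(l) l$h2_total, numeric(1)))
  se_int <- jack_se(vapply(loo, function(l) l$intercept, numeric(1)))

  tstat <- ifelse(se_d > 0, full$d / se_d, NA_real_)
  p_enr <- 2 * stats::pnorm(-abs(tstat))
  label <- ifelse(is.na(p_enr) | p_enr >= 0.05, "",
                  ifelse(full$enrichment < 1, "depletion", "enrichment"))

  out <- list(
    categories = data.frame(
      category = cats,
      tau = full$tau,
      se_tau = se_tau,
      prop_h2 = as.numeric(full$prop_h2),
      prop_snps = as.numeric(full$prop_snps),
      enrichment = as.numeric(full$enrichment),
      se_enrichment = se_enr,
      p_enrichment = as.numeric(p_enr),
      label = label,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    h2_total = full$h2_total, se_h2 = se_h2,
    intercept = full$intercept, se_intercept = se_int,
    mean_chi2 = mean(chi2), n_blocks = n_blocks,
    n_snps_regression = sum(ok), M = M_tot,
    chi2_max = thr
  )
  class(out) <- "partitioned_h2"
  out
}

#' @export
print.partitioned_h2 <- function(x, digits = 3, ...) {
  cat("Partitioned SNP-heritability (stratified LD-score regression)\n")
  cat(sprintf("  h2 = %.4f (SE %.4f)   intercept = %.4f (SE %.4f)   mean chi2 = %.3f\n",
              x$h2_total, x$se_h2, x$intercept, x$se_intercept, x$mean_chi2))
  cat(sprintf("  %d SNPs in regression of %d; %d jackknife blocks\n",
              x$n_snps_regression, x$M, x$n_blocks))
  df <- x$categories[, c("category", "prop_snps", "prop_h2", "enrichment",
                         "se_enrichment", "p_enrichment", "label")]
  print.data.frame(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.partitioned_h2 <- function(object, ...) object$categories

#' @export
coef.partitioned_h2 <- function(object, ...) {
  stats::setNames(object$categories$tau, object$categories$category)
}

#' Genetic correlation by bivariate LD-score regression
#'
#' Regresses the per-SNP product `z1 * z2` on `sqrt(N1 N2) * l_base / M`
#' with a free intercept (absorbing sample overlap) to estimate the genetic
#' covariance, and divides by the geometric mean of the two univariate
#' heritabilities: `rg = gencov / sqrt(h2_1 * h2_2)`. All three regressions
#' share weights and SNP-exclusion rules, so the genetic correlation of a
#' trait with itself is exactly 1. Standard error of the ratio comes from a
#' delete-one-block jackknife.
#'
#' @param stats1,stats2 `sumstats` data frames; only their SNP intersection
#'   (also present in `ldscores`) is used.
#' @param ldscores An `ld_score_table` with a base category.
#' @param n_blocks Jackknife blocks (default 200).
#' @return An `rg_result` with rg, se_rg, z, p, gencov, the two
#'   heritabilities, the three intercepts, and an out-of-range flag
#'   (|rg| > 1.25).
#' @export
fit_rg <- function(stats1, stats2, ldscores, n_blocks = 200) {
  stopifnot(inherits(ldscores, "ld_score_table"))
  ids <- intersect(intersect(stats1$id, stats2$id), ldscores$snps$id)
  if (!length(ids)) stop("empty SNP intersection", call. = FALSE)
  tab_idx <- which(ldscores$snps$id %in% ids)
  ord_ids <- ldscores$snps$id[tab_idx]
  s1 <- stats1[match(ord_ids, stats1$id), , drop = FALSE]
  s2 <- stats2[match(ord_ids, stats2$id), , drop = FALSE]
  lb_all <- ldscores$scores[tab_idx, "base"]
  M_tot <- nrow(ldscores$scores)

  thr1 <- max(80, 0.001 * stats::median(s1$n))
  thr2 <- max(80, 0.001 * stats::median(s2$n))
  ok <- s1$z^2 <= thr1 & s2$z^2 <= thr2 & !s1$missing & !s2$missing
  if (sum(ok) < n_blocks + 3)
    stop("too few SNPs retained for the cross-trait regression", call. = FALSE)

  z1 <- s1$z[ok]; z2 <- s2$z[ok]
  N1 <- s1$n[ok]; N2 <- s2$n[ok]
  lb <- lb_all[ok]

  designs <- list(
    h1 = list(x = N1 * lb / M_tot, y = z1^2, n = N1),
    h2 = list(x = N2 * lb / M_tot, y = z2^2, n = N2),
    gc = list(x = sqrt(N1 * N2) * lb / M_tot, y = z1 * z2, n = sqrt(N1 * N2))
  )
  prelim <- vapply(designs, function(d)
    stats::lm.fit(cbind(d$x, 1), d$y)$coefficients[1], numeric(1))
  hb <- pmin(pmax(prelim, 0), 1)
  hbar <- c(hb[1], hb[2], sqrt(hb[1] * hb[2]))
  lbw <- pmax(lb, 1)

  fits <- vector("list", 3)
  for (i in 1:3) {
    d <- designs[[i]]
    w <- 1 / (lbw * (1 + d$n * hbar[i] * lbw / M_tot)^2)
    fits[[i]] <- wls_jackknife(cbind(d$x, intercept = 1), d$y, w, n_blocks)
  }
  h1 <- fits[[1]]$theta[1]; h2v <- fits[[2]]$theta[1]; gencov <- fits[[3]]$theta[1]
  if (h1 <= 0 || h2v <= 0)
    stop("non-positive estimated heritability: rg undefined", call. = FALSE)
  rg <- gencov / sqrt(h1 * h2v)

  eps <- 1e-12
  rg_loo <- vapply(seq_len(n_blocks), function(b)
    fits[[3]]$loo[1, b] /
      sqrt(max(fits[[1]]$loo[1, b], eps) * max(fits[[2]]$loo[1, b], eps)),
    numeric(1))
  se_rg <- jack_se(rg_loo)
  se_gencov <- jack_se(fits[[3]]$loo[1, ])
  zstat <- if (se_rg > 0) rg / se_rg else Inf * sign(rg)

  structure(list(
    rg = rg, se_rg = se_rg, z = zstat, p = 2 * stats::pnorm(-abs(zstat)),
    gencov = gencov, se_gencov = se_gencov,
    h2_1 = h1, h2_2 = h2v,
    intercept_1 = fits[[1]]$theta[2], intercept_2 = fits[[2]]$theta[2],
    intercept_cross = fits[[3]]$theta[2],
    n_snps = sum(ok), n_blocks = n_blocks,
    out_of_range = abs(rg) > 1.25
  ), class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  cat(sprintf("Genetic correlation: rg = %.4f (SE %.4f), p = %.3g%s\n",
              x$rg, x$se_rg, x$p,
              if (x$out_of_range) "  [|rg| > 1.25: flagged]" else ""))
  cat(sprintf("  gencov = %.4f (SE %.4f); h2_1 = %.4f, h2_2 = %.4f\n",
              x$gencov, x$se_gencov, x$h2_1, x$h2_2))
  cat(sprintf("  intercepts: %.3f / %.3f / cross %.3f; %d SNPs, %d blocks\n",
              x$intercept_1, x$intercept_2, x$intercept_cross,
              x$n_snps, x$n_blocks))
  invisible(x)
}

#' @export
coef.rg_result <- function(object, ...) {
  c(rg = object$rg, gencov = object$gencov,
    h2_1 = object$h2_1, h2_2 = object$h2_2)
}
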