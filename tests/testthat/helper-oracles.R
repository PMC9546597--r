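# Independent oracles used to freeze expected values. Each is a deliberately
# naive implementation (brute force / normal equations / enumeration) that
# shares no code with the package paths it checks.

# OLS slope of y on x with intercept, by the normal equations.
oracle_ols_slope <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))[2]
}

# All-pairs bias-adjusted squared-correlation LD scores, ignoring any window.
oracle_ld_scores <- function(dosages, memb = NULL) {
  N <- nrow(dosages); M <- ncol(dosages)
  if (is.null(memb)) memb <- matrix(TRUE, M, 1)
  R <- stats::cor(dosages)
  adj <- R^2 - (1 - R^2) / (N - 2)
  out <- matrix(0, M, ncol(memb))
  for (c in seq_len(ncol(memb)))
    for (j in seq_len(M)) out[j, c] <- sum(adj[j, memb[, c]])
  out
}

# All-pairs r2 expansion of a seed SNP set.
oracle_ld_expand <- function(seed_idx, dosages, r2_min, strict = TRUE) {
  R2 <- stats::cor(dosages)^2
  hits <- seed_idx
  for (j in seed_idx) {
    sel <- if (strict) which(R2[j, ] > r2_min) else which(R2[j, ] >= r2_min - 1e-9)
    hits <- union(hits, sel)
  }
  sort(hits)
}

# Half-open interval intersection by exhaustive enumeration.
oracle_overlaps <- function(spans, intervals) {
  out <- NULL
  for (i in seq_len(nrow(spans))) for (k in seq_len(nrow(intervals))) {
    if (spans$chrom[i] == intervals$chrom[k] &&
        spans$start[i] < intervals$end[k] &&
        intervals$start[k] < spans$end[i])
      out <- rbind(out, data.frame(span = i, interval = k))
  }
  out
}

# Effective-test count via singular values (|eigenvalues| of a symmetric
# matrix) and the indicator-plus-fraction rule.
oracle_veff <- function(corr) {
  d <- svd(corr)$d
  sum((d >= 1) + (d - floor(d)))
}

# Benjamini-Hochberg step-up by direct enumeration of the rejection rank.
oracle_bh_reject <- function(p, m, alpha) {
  o <- order(p)
  k <- 0
  for (i in seq_along(p)) if (p[o][i] <= i * alpha / m) k <- i
  rej <- logical(length(p))
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}
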