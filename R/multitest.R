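#' Effective number of independent traits by eigenvalue decomposition
#'
#' Applies the spectral-decomposition estimator to a trait correlation
#' matrix: with eigenvalues `lambda_i`, the effective count is
#' `sum_i [ 1(|lambda_i| >= 1) + (|lambda_i| - floor(|lambda_i|)) ]`.
#' Perfectly correlated traits collapse to one effective test; independent
#' traits each count fully.
#'
#' Genetic-correlation matrices assembled from noisy pairwise fits need not
#' be positive semi-definite; use [repair_correlation()] first when needed.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @return A `veff_result`: eigenvalues (descending), veff_li, m.
#' @examples
#' veff_li(diag(10))$veff_li  # 10
#' @export
veff_li <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("input must be a symmetric matrix", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("input must have unit diagonal", call. = FALSE)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  a <- abs(ev)
  # epsilon-tolerant floor: an eigenvalue numerically just below an integer
  # must not contribute a spurious fractional part of ~1
  fl <- floor(a + 1e-9)
  veff <- sum((a >= 1 - 1e-9) + pmax(a - fl, 0))
  structure(list(eigenvalues = sort(ev, decreasing = TRUE),
                 veff_li = veff, m = nrow(corr)),
            class = "veff_result")
}

#' @export
print.veff_result <- function(x, ...) {
  cat(sprintf("Effective number of independent traits: %.2f of %d nominal\n",
              x$veff_li, x$m))
  invisible(x)
}

#' Repair an indefinite correlation matrix
#'
#' Clips negative eigenvalues at zero, reconstructs, and rescales to unit
#' diagonal — the minimal projection making a noisy pairwise
#' genetic-correlation matrix usable for spectral decomposition.
#'
#' @param corr Symmetric matrix with unit diagonal (possibly indefinite).
#' @return A positive semi-definite correlation matrix.
#' @export
repair_correlation <- function(corr) {
  corr <- as.matrix(corr)
  corr <- (corr + t(corr)) / 2
  eg <- eigen(corr, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  out <- eg$vectors %*% (lam * t(eg$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(corr)
  out
}

#' Benjamini-Hochberg FDR with an effective-test denominator
#'
#' Step-up false-discovery-rate control. When `m_eff` (e.g. the effective
#' number of independent traits from [veff_li()]) is smaller than the number
#' of p-values, the BH denominator m is replaced by `ceiling(m_eff)`;
#' otherwise standard BH applies. `m_eff` larger than the number of p-values
#' falls back to standard BH with a warning.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param m_eff Effective number of tests (>= 1), or NULL for standard BH.
#' @param alpha Target FDR level for the reject flags.
#' @return A data frame: p, q (monotone step-up q-values), reject.
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.04, 0.8), alpha = 0.05)
#' @export
bh_fdr <- function(pvalues, m_eff = NULL, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  n <- length(p)
  m <- n
  if (!is.null(m_eff)) {
    if (m_eff < 1) stop("m_eff must be >= 1", call. = FALSE)
    if (m_eff > n) {
      warning("m_eff exceeds the number of p-values; using standard BH",
              call. = FALSE)
    } else if (m_eff < n) {
      m <- as.integer(ceiling(m_eff))
    }
  }
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  data.frame(p = p, q = q, reject = q <= alpha)
}
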