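#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Banded partitioned LD-score accumulation over position-sorted,
// column-standardized genotypes of one chromosome. For every pair (j, k)
// with |pos_k - pos_j| <= window the bias-adjusted squared correlation
// r2 - (1 - r2) / (N - 2) is added to the scores of both SNPs for every
// category containing the partner (self-pair counted once).
// [[Rcpp::export]]
NumericMatrix cpp_band_ldscores(NumericMatrix Gs, NumericVector pos,
                                double window, NumericMatrix memb) {
  const int N = Gs.nrow(), M = Gs.ncol(), C = memb.ncol();
  NumericMatrix scores(M, C);
  const int n4 = N - (N % 4);
  for (int j = 0; j < M; ++j) {
    const double* xj = &Gs(0, j);
    for (int k = j; k < M && pos[k] - pos[j] <= window; ++k) {
      const double* xk = &Gs(0, k);
      // four accumulators so the reduction pipelines without -ffast-math
      double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
      for (int i = 0; i < n4; i += 4) {
        s0 += xj[i] * xk[i];
        s1 += xj[i + 1] * xk[i + 1];
        s2 += xj[i + 2] * xk[i + 2];
        s3 += xj[i + 3] * xk[i + 3];
      }
      for (int i = n4; i < N; ++i) s0 += xj[i] * xk[i];
      const double r = (s0 + s1 + s2 + s3) / N;
      const double r2 = r * r;
      const double adj = r2 - (1.0 - r2) / (N - 2.0);
      for (int c = 0; c < C; ++c) {
        const double mk = memb(k, c), mj = memb(j, c);
        if (mk != 0.0) scores(j, c) += adj * mk;
        if (k != j && mj != 0.0) scores(k, c) += adj * mj;
      }
    }
  }
  return scores;
}

// Latent-Gaussian threshold dosage simulation. One latent normal per
// genotype: lat = sr_b * u_block(individual) + se_b * noise, dosage =
// 1(lat < thr1) + 1(lat < thr2), giving binomial(2, p) margins under
// Hardy-Weinberg with controllable per-block exchangeable latent
// correlation. Latents come from a dedicated Mersenne Twister seeded from
// R's RNG, so the draw is reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_simulate_dosages(int N, NumericMatrix thr1,
                                   NumericMatrix thr2, IntegerVector subpop,
                                   IntegerVector block_map,
                                   NumericVector sr_block,
                                   NumericVector se_block) {
  const int M = block_map.size();
  NumericMatrix dos(N, M);
  std::vector<double> u(N, 0.0);
  const uint64_t seed =
      (uint64_t)(unif_rand() * 4294967295.0) << 16 ^
      (uint64_t)(unif_rand() * 4294967295.0);
  std::mt19937_64 eng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  int cur_block = -1;
  for (int j = 0; j < M; ++j) {
    const int b = block_map[j] - 1;
    const double sr = sr_block[b], se = se_block[b];
    if (block_map[j] != cur_block) {
      cur_block = block_map[j];
      for (int i = 0; i < N; ++i) u[i] = gauss(eng);
    }
    const double t1a = thr1(0, j), t1b = thr1(1, j);
    const double t2a = thr2(0, j), t2b = thr2(1, j);
    double* dj = &dos(0, j);
    for (int i = 0; i < N; ++i) {
      const double lat = sr * u[i] + se * gauss(eng);
      const double t1 = subpop[i] ? t1b : t1a;
      const double t2 = subpop[i] ? t2b : t2a;
      dj[i] = (lat < t1 ? 1.0 : 0.0) + (lat < t2 ? 1.0 : 0.0);
    }
  }
  return dos;
}

// One-pass column means and population standard deviations.
// [[Rcpp::export]]
List cpp_col_moments(NumericMatrix X) {
  const int N = X.nrow(), M = X.ncol();
  NumericVector mu(M), sd(M);
  for (int j = 0; j < M; ++j) {
    const double* x = &X(0, j);
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < N; ++i) { s += x[i]; ss += x[i] * x[i]; }
    mu[j] = s / N;
    const double v = ss / N - mu[j] * mu[j];
    sd[j] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// One-pass column standardization; columns with sd below tol are zeroed.
// [[Rcpp::export]]
NumericMatrix cpp_standardize(NumericMatrix X, NumericVector mu,
                              NumericVector sd, double tol) {
  const int N = X.nrow(), M = X.ncol();
  NumericMatrix out(N, M);
  for (int j = 0; j < M; ++j) {
    const double* x = &X(0, j);
    double* o = &out(0, j);
    if (sd[j] < tol) continue;
    const double m = mu[j], inv = 1.0 / sd[j];
    for (int i = 0; i < N; ++i) o[i] = (x[i] - m) * inv;
  }
  return out;
}

// g = X beta for a small number of trait columns, one streaming pass over X.
// [[Rcpp::export]]
NumericMatrix cpp_genetic_values(NumericMatrix X, NumericMatrix beta) {
  const int N = X.nrow(), M = X.ncol(), T = beta.ncol();
  NumericMatrix g(N, T);
  for (int j = 0; j < M; ++j) {
    const double* x = &X(0, j);
    for (int t = 0; t < T; ++t) {
      const double b = beta(j, t);
      if (b == 0.0) continue;
      double* gt = &g(0, t);
      for (int i = 0; i < N; ++i) gt[i] += x[i] * b;
    }
  }
  return g;
}
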