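#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stable log(plogis(x)) and log(1 - plogis(x)).
static inline double log_plogis(double x) {
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// Binomial coefficient table for the truncated mixture sum.
// A(N, s) = sum_j lchoose(N, y[s, j]) over non-missing visits j,
// defined for N >= max_j y[s, j] (rows below that are never used).
// [[Rcpp::export]]
NumericMatrix nm_lchoose_table(IntegerMatrix y, int K) {
  int n = y.nrow(), J = y.ncol();
  NumericMatrix A(K + 1, n);
  for (int s = 0; s < n; ++s) {
    int maxy = 0;
    for (int j = 0; j < J; ++j)
      if (y(s, j) != NA_INTEGER && y(s, j) > maxy) maxy = y(s, j);
    for (int N = 0; N < maxy; ++N) A(N, s) = R_NegInf;
    for (int N = maxy; N <= K; ++N) {
      double a = 0.0;
      for (int j = 0; j < J; ++j) {
        int yy = y(s, j);
        if (yy == NA_INTEGER) continue;
        a += R::lchoose((double) N, (double) yy);
      }
      A(N, s) = a;
    }
  }
  return A;
}

// Marginal log-likelihood per site-year:
//   log sum_{N=maxy}^{K} Poisson(N; lambda) * prod_j Binomial(y_j; N, p_j)
// with eta_lam = log lambda and eta_p = logit p, computed in log space.
// Missing visits (NA counts) contribute nothing to the product.
// [[Rcpp::export]]
NumericVector nm_siteyear_loglik(NumericVector eta_lam, NumericMatrix eta_p,
                                 IntegerMatrix y, NumericMatrix A,
                                 IntegerVector maxy, int K) {
  int n = y.nrow(), J = y.ncol();
  NumericVector out(n);
  std::vector<double> lfact(K + 1), term(K + 1);
  for (int N = 0; N <= K; ++N) lfact[N] = R::lgammafn((double) N + 1.0);
  for (int s = 0; s < n; ++s) {
    double loglam = eta_lam[s];
    double lam = std::exp(loglam);
    if (!R_finite(lam)) { out[s] = R_NegInf; continue; }
    double B = 0.0, C = 0.0;
    for (int j = 0; j < J; ++j) {
      int yy = y(s, j);
      if (yy == NA_INTEGER) continue;
      double x = eta_p(s, j);
      double logp = log_plogis(x);
      double logq = logp - x;           // log(1 - p)
      B += yy * (logp - logq);
      C += logq;
    }
    int lo = maxy[s], hi = lo;
    double m = R_NegInf, prev = R_NegInf;
    for (int N = lo; N <= K; ++N) {
      double t = -lam + N * loglam - lfact[N] + A(N, s) + B + N * C;
      term[N] = t;
      hi = N;
      if (t > m) m = t;
      // the summand is unimodal in N: once past the mode and 46 nats below
      // the maximum, the remaining tail is < 1e-20 of the sum
      else if (t < prev && t < m - 46.0) break;
      prev = t;
    }
    if (!R_finite(m)) { out[s] = R_NegInf; continue; }
    double acc = 0.0;
    for (int N = lo; N <= hi; ++N) acc += std::exp(term[N] - m);
    out[s] = m + std::log(acc);
  }
  return out;
}

// One draw of the latent abundance N_s from its discrete full conditional
// N_s | y_s, lambda_s, p_s on {maxy_s, ..., K}, for every site-year.
// Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector nm_draw_latent(NumericVector eta_lam, NumericMatrix eta_p,
                             IntegerMatrix y, NumericMatrix A,
                             IntegerVector maxy, int K) {
  int n = y.nrow(), J = y.ncol();
  IntegerVector out(n);
  std::vector<double> lfact(K + 1), term(K + 1);
  for (int N = 0; N <= K; ++N) lfact[N] = R::lgammafn((double) N + 1.0);
  for (int s = 0; s < n; ++s) {
    double loglam = eta_lam[s];
    double lam = std::exp(loglam);
    double B = 0.0, C = 0.0;
    for (int j = 0; j < J; ++j) {
      int yy = y(s, j);
      if (yy == NA_INTEGER) continue;
      double x = eta_p(s, j);
      double logp = log_plogis(x);
      double logq = logp - x;
      B += yy * (logp - logq);
      C += logq;
    }
    int lo = maxy[s], hi = lo;
    double m = R_NegInf, prev = R_NegInf;
    for (int N = lo; N <= K; ++N) {
      double t = -lam + N * loglam - lfact[N] + A(N, s) + B + N * C;
      term[N] = t;
      hi = N;
      if (t > m) m = t;
      else if (t < prev && t < m - 46.0) break;
      prev = t;
    }
    double tot = 0.0;
    for (int N = lo; N <= hi; ++N) { term[N] = std::exp(term[N] - m); tot += term[N]; }
    double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
    int pick = hi;
    for (int N = lo; N <= hi; ++N) {
      acc += term[N];
      if (u <= acc) { pick = N; break; }
    }
    out[s] = pick;
  }
  return out;
}
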