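#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Forward-algorithm log-likelihood with per-step rescaling.
// logdens: T x S matrix of per-observation log emission densities,
// trans: S x S row-stochastic transition matrix, init: length-S simplex.
// [[Rcpp::export]]
double cpp_forward_loglik(const NumericMatrix& logdens,
                          const NumericMatrix& trans,
                          const NumericVector& init) {
  const int T = logdens.nrow(), S = logdens.ncol();
  if (T == 0) return 0.0;
  std::vector<double> alpha(S), tmp(S);
  double ll = 0.0;

  double m = logdens(0, 0);
  for (int s = 1; s < S; ++s) m = std::max(m, logdens(0, s));
  double tot = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha[s] = init[s] * std::exp(logdens(0, s) - m);
    tot += alpha[s];
  }
  ll += std::log(tot) + m;
  for (int s = 0; s < S; ++s) alpha[s] /= tot;

  for (int t = 1; t < T; ++t) {
    m = logdens(t, 0);
    for (int s = 1; s < S; ++s) m = std::max(m, logdens(t, s));
    tot = 0.0;
    for (int s = 0; s < S; ++s) {
      double a = 0.0;
      for (int r = 0; r < S; ++r) a += alpha[r] * trans(r, s);
      tmp[s] = a * std::exp(logdens(t, s) - m);
      tot += tmp[s];
    }
    if (!(tot > 0.0) || !std::isfinite(tot)) return R_NegInf;
    ll += std::log(tot) + m;
    for (int s = 0; s < S; ++s) alpha[s] = tmp[s] / tot;
  }
  return ll;
}

// Full negative log-likelihood of the 3-state gamma / von Mises HMM in
// one pass (emissions + forward recursion); turns may be NA (step-only
// contribution). Used by the optimizer where per-eval cost matters.
// [[Rcpp::export]]
double cpp_hmm_nll(const NumericVector& step, const NumericVector& turn,
                   const NumericVector& shape, const NumericVector& scale,
                   const NumericVector& mu, const NumericVector& kappa,
                   const NumericMatrix& trans, const NumericVector& init) {
  const int T = step.size(), S = shape.size();
  std::vector<double> lgam(S), lognorm_vm(S), logscale(S);
  for (int s = 0; s < S; ++s) {
    lgam[s] = R::lgammafn(shape[s]);
    logscale[s] = std::log(scale[s]);
    // log I0(kappa) from the exponentially scaled Bessel
    lognorm_vm[s] = std::log(2.0 * M_PI) +
      std::log(R::bessel_i(kappa[s], 0.0, 2.0)) + kappa[s];
  }
  std::vector<double> alpha(S), tmp(S), ld(S);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    const double st = step[t];
    const bool has_turn = !NumericVector::is_na(turn[t]);
    double m = R_NegInf;
    for (int s = 0; s < S; ++s) {
      double v = (shape[s] - 1.0) * std::log(st) - st / scale[s] -
        lgam[s] - shape[s] * logscale[s];
      if (has_turn) v += kappa[s] * std::cos(turn[t] - mu[s]) - lognorm_vm[s];
      ld[s] = v;
      if (v > m) m = v;
    }
    double tot = 0.0;
    if (t == 0) {
      for (int s = 0; s < S; ++s) {
        alpha[s] = init[s] * std::exp(ld[s] - m);
        tot += alpha[s];
      }
    } else {
      for (int s = 0; s < S; ++s) {
        double a = 0.0;
        for (int r = 0; r < S; ++r) a += alpha[r] * trans(r, s);
        tmp[s] = a * std::exp(ld[s] - m);
        tot += tmp[s];
      }
      for (int s = 0; s < S; ++s) alpha[s] = tmp[s];
    }
    if (!(tot > 0.0) || !std::isfinite(tot)) return R_PosInf;
    ll += std::log(tot) + m;
    for (int s = 0; s < S; ++s) alpha[s] /= tot;
  }
  return -ll;
}

// Viterbi most-probable state path (1-based labels).
// [[Rcpp::export]]
IntegerVector cpp_viterbi(const NumericMatrix& logdens,
                          const NumericMatrix& log_trans,
                          const NumericVector& log_init) {
  const int T = logdens.nrow(), S = logdens.ncol();
  IntegerVector path(T);
  if (T == 0) return path;
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);
  for (int s = 0; s < S; ++s) delta(0, s) = log_init[s] + logdens(0, s);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf; int arg = 0;
      for (int r = 0; r < S; ++r) {
        double v = delta(t - 1, r) + log_trans(r, s);
        if (v > best) { best = v; arg = r; }
      }
      delta(t, s) = best + logdens(t, s);
      psi(t, s) = arg;
    }
  }
  double best = R_NegInf; int arg = 0;
  for (int s = 0; s < S; ++s)
    if (delta(T - 1, s) > best) { best = delta(T - 1, s); arg = s; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Gaussian-kernel density sum on a rectangular grid for a full SPD
// bandwidth matrix H. hinv: 2x2 inverse of H, dens normalised by
// 1 / (n * 2 * pi * sqrt(det(H))).
// [[Rcpp::export]]
NumericMatrix cpp_kde_grid(const NumericVector& px, const NumericVector& py,
                           const NumericVector& gx, const NumericVector& gy,
                           const NumericMatrix& hinv, double det_h) {
  const int n = px.size(), nx = gx.size(), ny = gy.size();
  const double a = hinv(0, 0), b = hinv(0, 1), c = hinv(1, 1);
  const double norm = 1.0 / (n * 2.0 * M_PI * std::sqrt(det_h));
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        const double dx = gx[i] - px[k], dy = gy[j] - py[k];
        const double q = a * dx * dx + 2.0 * b * dx * dy + c * dy * dy;
        if (q < 50.0) acc += std::exp(-0.5 * q);
      }
      out(i, j) = norm * acc;
    }
  }
  return out;
}

// Least-squares cross-validation criterion for a bivariate Gaussian
// kernel with full bandwidth matrix H:
//   LSCV(H) = n^-2 sum_{ij} K_{2H}(di - dj) - 2/(n(n-1)) sum_{i!=j} K_H(.)
// [[Rcpp::export]]
double cpp_lscv_crit(const NumericVector& px, const NumericVector& py,
                     const NumericMatrix& hinv, double det_h) {
  const int n = px.size();
  const double a = hinv(0, 0), b = hinv(0, 1), c = hinv(1, 1);
  const double c1 = 1.0 / (2.0 * M_PI * std::sqrt(4.0 * det_h)); // |2H| = 4|H|
  const double c2 = 1.0 / (2.0 * M_PI * std::sqrt(det_h));
  double s2h = 0.0, sh = 0.0; // off-diagonal sums (pairs counted once)
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      const double dx = px[i] - px[j], dy = py[i] - py[j];
      const double q = a * dx * dx + 2.0 * b * dx * dy + c * dy * dy;
      if (q < 200.0) {
        s2h += std::exp(-0.25 * q); // (2H)^-1 = hinv / 2
        sh  += std::exp(-0.5 * q);
      }
    }
  }
  const double int_f2 = (c1 * (2.0 * s2h + n)) / ((double)n * n);
  const double loo    = (2.0 * c2 * 2.0 * sh) / ((double)n * (n - 1.0));
  return int_f2 - loo;
}

// Centered rolling lower-quantile baseline (type-7 quantile); window
// shrinks symmetrically at the edges.
// [[Rcpp::export]]
NumericVector cpp_rolling_quantile(const NumericVector& x, int window,
                                   double q) {
  const int n = x.size();
  NumericVector out(n);
  const int half = window / 2;
  std::vector<double> buf;
  buf.reserve(window + 1);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - half);
    const int hi = std::min(n - 1, i + half);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const int m = (int)buf.size();
    const double h = (m - 1) * q;
    const int k = (int)std::floor(h);
    std::nth_element(buf.begin(), buf.begin() + k, buf.end());
    double v = buf[k];
    if (k + 1 < m) {
      double v2 = *std::min_element(buf.begin() + k + 1, buf.end());
      v += (h - k) * (v2 - v);
    }
    out[i] = v;
  }
  return out;
}
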