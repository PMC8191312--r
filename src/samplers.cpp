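#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Landscape family codes shared with R/landscape.R:
//   0 flat, 1 harmonic, 2 double-well, 3 tilted double-well, 4 gaussian-wells
// Parameter layouts are documented in makeLandscape().

static inline void grad_eval(int family, const std::vector<double> &par,
                             const double *x, int dim, double *g) {
  switch (family) {
  case 0: // flat: U = 0
    for (int d = 0; d < dim; ++d) g[d] = 0.0;
    break;
  case 1: // harmonic: U = 0.5 * kappa * |x|^2
    for (int d = 0; d < dim; ++d) g[d] = par[0] * x[d];
    break;
  case 2: // double-well (1D): U = h * (x^2 - 1)^2
    g[0] = 4.0 * par[0] * x[0] * (x[0] * x[0] - 1.0);
    break;
  case 3: // tilted double-well (1D): U = h * (x^2 - 1)^2 + a * x
    g[0] = 4.0 * par[0] * x[0] * (x[0] * x[0] - 1.0) + par[1];
    break;
  case 4: { // gaussian wells + harmonic confinement (2D)
    // par = [kappa, sigma, d1, ax1, ay1, d2, ax2, ay2, ...]
    const double kappa = par[0], s2 = par[1] * par[1];
    g[0] = kappa * x[0];
    g[1] = kappa * x[1];
    const int nw = (static_cast<int>(par.size()) - 2) / 3;
    for (int w = 0; w < nw; ++w) {
      const double d = par[2 + 3 * w];
      const double dx = x[0] - par[3 + 3 * w];
      const double dy = x[1] - par[4 + 3 * w];
      const double e = std::exp(-(dx * dx + dy * dy) / (2.0 * s2));
      g[0] += d * e * dx / s2;
      g[1] += d * e * dy / s2;
    }
    break;
  }
  default:
    stop("unknown landscape family code %d", family);
  }
}

// [[Rcpp::export]]
NumericVector cpp_grad(int family, NumericVector params, NumericVector x) {
  std::vector<double> par(params.begin(), params.end());
  int dim = x.size();
  NumericVector g(dim);
  grad_eval(family, par, REAL(x), dim, REAL(g));
  return g;
}

// Euler-Maruyama integration of overdamped Langevin dynamics:
//   x <- x - (D/kT) * gradU(x) * dt + sqrt(2 D dt) * xi
// Every `stride`-th configuration is recorded (the initial point included).
// [[Rcpp::export]]
NumericMatrix cpp_langevin(int family, NumericVector params, NumericVector x0,
                           int nSteps, double dt, double D, double kT,
                           int stride) {
  const int dim = x0.size();
  const int nOut = nSteps / stride + 1;
  NumericMatrix out(nOut, dim);
  std::vector<double> par(params.begin(), params.end());
  std::vector<double> x(x0.begin(), x0.end()), g(dim);
  const double mob = D / kT * dt, amp = std::sqrt(2.0 * D * dt);
  for (int d = 0; d < dim; ++d) out(0, d) = x[d];
  int row = 1;
  for (int t = 1; t <= nSteps; ++t) {
    grad_eval(family, par, x.data(), dim, g.data());
    for (int d = 0; d < dim; ++d) {
      if (!std::isfinite(g[d]))
        stop("non-finite potential gradient at coordinate (%f) [dimension %d, step %d]",
             x[d], d + 1, t);
      x[d] += -mob * g[d] + amp * norm_rand();
    }
    if (t % stride == 0) {
      for (int d = 0; d < dim; ++d) out(row, d) = x[d];
      ++row;
    }
  }
  return out;
}

// Sample a discrete Markov chain from cumulative row-stochastic matrix cumT
// (states 0-based internally; R wrapper shifts to 1-based).
// [[Rcpp::export]]
IntegerVector cpp_sample_chain(NumericMatrix cumT, int nSteps, int start0) {
  const int k = cumT.ncol();
  IntegerVector out(nSteps);
  int s = start0;
  out[0] = s;
  for (int t = 1; t < nSteps; ++t) {
    const double u = unif_rand();
    int j = 0;
    while (j < k - 1 && u > cumT(s, j)) ++j;
    s = j;
    out[t] = s;
  }
  return out;
}

// Sliding-window modal filter for discrete state sequences: entry t holds the
// most frequent state among s[t..t+w-1] (earliest-seen state wins ties).
// [[Rcpp::export]]
IntegerVector cpp_mode_filter(IntegerVector s, int w) {
  const int n = s.size();
  const int m = n - w + 1;
  if (m <= 0) return IntegerVector(0);
  IntegerVector out(m);
  int maxState = 0;
  for (int i = 0; i < n; ++i) if (s[i] > maxState) maxState = s[i];
  std::vector<int> cnt(maxState + 1, 0);
  for (int t = 0; t < m; ++t) {
    int best = s[t], bestCnt = 0;
    for (int j = 0; j < w; ++j) cnt[s[t + j]] += 1;
    for (int j = 0; j < w; ++j) {
      const int st = s[t + j];
      if (cnt[st] > bestCnt) { bestCnt = cnt[st]; best = st; }
    }
    for (int j = 0; j < w; ++j) cnt[s[t + j]] = 0;
    out[t] = best;
  }
  return out;
}
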