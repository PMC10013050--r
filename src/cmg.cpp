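#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Coupled Mackey-Glass integration: fixed-step classical RK4 with the
// delayed state taken from the stored grid (method of steps). The delay is
// an exact multiple of the step, so stage times fall on grid nodes or grid
// midpoints; midpoints use cubic Hermite interpolation from stored values
// and derivatives.
//
// xdot_j = -0.1 x_j + sum_i C(i,j) * x_i(t - delay) / (1 + x_i(t - delay)^10)
//
// C includes any self-coupling on its diagonal.

static inline double mg_gain(double u) {
  double u2 = u * u, u4 = u2 * u2;
  return u / (1.0 + u4 * u4 * u2);
}

// [[Rcpp::export]]
NumericMatrix cmg_integrate(NumericMatrix C, NumericVector history, double h,
                            int ndelay, int sampleSteps, int nSamples,
                            int transientSamples) {
  const int K = C.nrow();
  if (C.ncol() != K) stop("coupling matrix must be square");
  if (ndelay < 1) stop("delay must be at least one integration step");
  const int records = transientSamples + nSamples;
  const long totalSteps = (long)records * sampleSteps;
  const long G = ndelay + totalSteps + 1;  // grid nodes incl. history

  // sparse-by-column driver lists: drivers[j] = rows i with C(i,j) != 0
  std::vector<std::vector<int> > drivers(K);
  std::vector<std::vector<double> > dw(K);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i)
      if (C(i, j) != 0.0) { drivers[j].push_back(i); dw[j].push_back(C(i, j)); }

  std::vector<double> X((size_t)G * K), F((size_t)G * K, 0.0);
  std::vector<double> gd1(K), gd2(K), gd3(K), k1(K), k2(K), k3(K), k4(K), xs(K);

  for (long i = 0; i <= ndelay; ++i)
    for (int j = 0; j < K; ++j) X[(size_t)i * K + j] = history[j];

  const double hh = 0.5 * h;
  for (long i = ndelay; i < G - 1; ++i) {
    const double *x0 = &X[(size_t)i * K];
    const double *xa = &X[(size_t)(i - ndelay) * K];       // t - delay
    const double *xb = &X[(size_t)(i - ndelay + 1) * K];   // t + h - delay
    const double *fa = &F[(size_t)(i - ndelay) * K];
    const double *fb = &F[(size_t)(i - ndelay + 1) * K];
    for (int j = 0; j < K; ++j) {
      // Hermite cubic at the interval midpoint
      double xm = 0.5 * (xa[j] + xb[j]) + 0.125 * h * (fa[j] - fb[j]);
      gd1[j] = mg_gain(xa[j]);
      gd2[j] = mg_gain(xm);
      gd3[j] = mg_gain(xb[j]);
    }
    double *f0 = &F[(size_t)i * K];
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (size_t q = 0; q < drivers[j].size(); ++q) s += dw[j][q] * gd1[drivers[j][q]];
      k1[j] = -0.1 * x0[j] + s;
      f0[j] = k1[j];
    }
    for (int j = 0; j < K; ++j) xs[j] = x0[j] + hh * k1[j];
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (size_t q = 0; q < drivers[j].size(); ++q) s += dw[j][q] * gd2[drivers[j][q]];
      k2[j] = -0.1 * xs[j] + s;
    }
    for (int j = 0; j < K; ++j) xs[j] = x0[j] + hh * k2[j];
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (size_t q = 0; q < drivers[j].size(); ++q) s += dw[j][q] * gd2[drivers[j][q]];
      k3[j] = -0.1 * xs[j] + s;
    }
    for (int j = 0; j < K; ++j) xs[j] = x0[j] + h * k3[j];
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (size_t q = 0; q < drivers[j].size(); ++q) s += dw[j][q] * gd3[drivers[j][q]];
      k4[j] = -0.1 * xs[j] + s;
    }
    double *x1 = &X[(size_t)(i + 1) * K];
    for (int j = 0; j < K; ++j) {
      x1[j] = x0[j] + h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(x1[j]) || std::fabs(x1[j]) > 1e6)
        stop("Mackey-Glass integration became unstable at node %d", j + 1);
    }
  }

  NumericMatrix out(nSamples, K);
  for (int m = 0; m < nSamples; ++m) {
    long i = ndelay + (long)(transientSamples + m + 1) * sampleSteps;
    if (i > G - 1) i = G - 1;
    for (int j = 0; j < K; ++j) out(m, j) = X[(size_t)i * K + j];
  }
  return out;
}
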