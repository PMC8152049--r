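#include <Rcpp.h>
using namespace Rcpp;

// Convolution y(t) = \int_0^t exp(-alpha (t-u)) f(u) du on an arbitrary
// increasing grid, exact for piecewise-linear f. Recursive update:
//   y[n] = exp(-alpha*dt) * y[n-1] + \int_0^dt exp(-alpha*s) f(t[n]-s) ds
// with f linear on [t[n-1], t[n]]. A0 = \int exp(-alpha s) ds,
// A1 = \int s exp(-alpha s) ds; series expansions guard small alpha*dt.

static inline void moments(double alpha, double dt, double &A0, double &A1) {
  double x = alpha * dt;
  if (std::abs(x) < 1e-6) {
    A0 = dt * (1.0 - x / 2.0 + x * x / 6.0);
    A1 = dt * dt * (0.5 - x / 3.0 + x * x / 8.0);
  } else {
    double em = std::exp(-x);
    A0 = -std::expm1(-x) / alpha;
    A1 = (-std::expm1(-x) - x * em) / (alpha * alpha);
  }
}

// [[Rcpp::export]]
NumericVector expconv_cpp(double alpha, NumericVector t, NumericVector f) {
  int n = t.size();
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    double dt = t[i] - t[i - 1];
    double A0, A1;
    moments(alpha, dt, A0, A1);
    // f(t[i]-s) = f[i] + (f[i-1]-f[i]) * s/dt for s in [0, dt]
    double inc = f[i] * A0 + (f[i - 1] - f[i]) * A1 / dt;
    y[i] = std::exp(-alpha * dt) * y[i - 1] + inc;
  }
  return y;
}
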