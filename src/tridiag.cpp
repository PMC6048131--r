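#include <Rcpp.h>
using namespace Rcpp;

// Thomas solve of a tridiagonal system A x = d.
// sub[i] multiplies x[i-1] in row i (sub[0] unused), super[i] multiplies
// x[i+1] (super[G-1] unused).  Overwrites work arrays; returns x.
static void thomas(const std::vector<double>& sub,
                   const std::vector<double>& diag,
                   const std::vector<double>& super,
                   std::vector<double>& d, std::vector<double>& cp,
                   std::vector<double>& x) {
  const int n = diag.size();
  cp[0] = super[0] / diag[0];
  d[0] = d[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - sub[i] * cp[i - 1];
    cp[i] = super[i] / m;
    d[i] = (d[i] - sub[i] * d[i - 1]) / m;
  }
  x[n - 1] = d[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = d[i] - cp[i] * x[i + 1];
}

// Stationary state of the finite-volume operator: solve L f = -src.
// [[Rcpp::export(name = ".tridiag_stationary")]]
NumericVector tridiag_stationary(NumericVector sub, NumericVector diag,
                                 NumericVector super, NumericVector src) {
  const int n = diag.size();
  std::vector<double> a(n), b(n), c(n), d(n), cp(n), x(n);
  for (int i = 0; i < n; ++i) {
    a[i] = -sub[i]; b[i] = -diag[i]; c[i] = -super[i]; d[i] = src[i];
  }
  thomas(a, b, c, d, cp, x);
  return NumericVector(x.begin(), x.end());
}

// Backward-Euler integration of df/dt = L f + src over nsteps steps of
// size dt.  The factorization of (I - dt L) is reused across steps.
// [[Rcpp::export(name = ".tridiag_be_steps")]]
NumericVector tridiag_be_steps(NumericVector f0, NumericVector sub,
                               NumericVector diag, NumericVector super,
                               NumericVector src, double dt, int nsteps) {
  const int n = diag.size();
  std::vector<double> a(n), b(n), c(n), cp(n), f(n), d(n), x(n);
  for (int i = 0; i < n; ++i) {
    a[i] = -dt * sub[i];
    b[i] = 1.0 - dt * diag[i];
    c[i] = -dt * super[i];
    f[i] = f0[i];
  }
  // Pre-factor: store the normalized super-diagonal and row multipliers.
  std::vector<double> m(n);
  cp[0] = c[0] / b[0];
  m[0] = b[0];
  for (int i = 1; i < n; ++i) {
    m[i] = b[i] - a[i] * cp[i - 1];
    cp[i] = c[i] / m[i];
  }
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < n; ++i) d[i] = f[i] + dt * src[i];
    d[0] /= m[0];
    for (int i = 1; i < n; ++i) d[i] = (d[i] - a[i] * d[i - 1]) / m[i];
    f[n - 1] = d[n - 1];
    for (int i = n - 2; i >= 0; --i) f[i] = d[i] - cp[i] * f[i + 1];
  }
  return NumericVector(f.begin(), f.end());
}
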