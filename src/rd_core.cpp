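#include <Rcpp.h>
using namespace Rcpp;

// Hot loop of the operator-splitting reaction-diffusion integrator:
// per diffusion step, n_sub forward-Euler reaction substeps
// (f = u1^2 u2 - u1, applied +f/-f) followed by one explicit diffusion
// step per species. Periodic boundaries throughout. The uFDM path uses
// precomputed linear-interpolation brackets (lo, w) for the phantom-point
// estimates; the monotone-cubic path stays in R.
//
// solver: 0 = plain 1D stencil, 1 = 2D stencil (column-major N x M),
//         2 = 1D-uFDM with linear off-plane interpolation.

static void euler_reactions(double* u1, double* u2, int n,
                            double dtR, int n_sub) {
  for (int s = 0; s < n_sub; ++s) {
    for (int i = 0; i < n; ++i) {
      const double f = u1[i] * u1[i] * u2[i] - u1[i];
      u1[i] += dtR * f;
      u2[i] -= dtR * f;
    }
  }
}

static void step_1d(const double* u, double* out, int N, double d) {
  for (int i = 0; i < N; ++i) {
    const int im = (i == 0) ? N - 1 : i - 1;
    const int ip = (i == N - 1) ? 0 : i + 1;
    out[i] = u[i] + d * (u[im] - 2.0 * u[i] + u[ip]);
  }
}

static void step_2d(const double* u, double* out, int N, int M,
                    double dx, double dy) {
  for (int j = 0; j < M; ++j) {
    const int jm = (j == 0) ? M - 1 : j - 1;
    const int jp = (j == M - 1) ? 0 : j + 1;
    const double* c = u + (size_t)j * N;
    const double* ym = u + (size_t)jm * N;
    const double* yp = u + (size_t)jp * N;
    double* o = out + (size_t)j * N;
    for (int i = 0; i < N; ++i) {
      const int im = (i == 0) ? N - 1 : i - 1;
      const int ip = (i == N - 1) ? 0 : i + 1;
      o[i] = c[i] + dx * (c[im] - 2.0 * c[i] + c[ip]) +
                    dy * (ym[i] - 2.0 * c[i] + yp[i]);
    }
  }
}

// One explicit uFDM step; `lo` holds 0-based indices into the half profile
// u[c0 .. N-1] (c0 = N/2 - 1 in 0-based terms) and `w` the linear weights
// toward lo + 1, both precomputed from the phantom distances.
static void step_ufdm(const double* u, double* out, int N,
                      const int* lo, const double* w,
                      int c0, double dx, double dy2) {
  const double* half = u + c0;
  for (int n = 0; n < N; ++n) {
    const int im = (n == 0) ? N - 1 : n - 1;
    const int ip = (n == N - 1) ? 0 : n + 1;
    const double ut = half[lo[n]] * (1.0 - w[n]) + half[lo[n] + 1] * w[n];
    out[n] = u[n] + dx * (u[im] - 2.0 * u[n] + u[ip]) + dy2 * (ut - u[n]);
  }
}

// [[Rcpp::export(name = ".rd_advance")]]
List rd_advance(NumericVector u1, NumericVector u2, int N, int M, int solver,
                double d1x, double d1y, double d2x, double d2y,
                double dtR, int n_sub, int nsteps,
                IntegerVector lo, NumericVector w) {
  const int n = u1.size();
  std::vector<double> a1(u1.begin(), u1.end()), a2(u2.begin(), u2.end());
  std::vector<double> b1(n), b2(n);
  double *p1 = a1.data(), *p2 = a2.data(), *q1 = b1.data(), *q2 = b2.data();
  const int* plo = lo.size() ? &lo[0] : nullptr;
  const double* pw = w.size() ? &w[0] : nullptr;
  const int c0 = N / 2 - 1;  // 0-based index of the patch centre

  for (int s = 0; s < nsteps; ++s) {
    euler_reactions(p1, p2, n, dtR, n_sub);
    if (solver == 0) {
      step_1d(p1, q1, N, d1x);
      step_1d(p2, q2, N, d2x);
    } else if (solver == 1) {
      step_2d(p1, q1, N, M, d1x, d1y);
      step_2d(p2, q2, N, M, d2x, d2y);
    } else {
      step_ufdm(p1, q1, N, plo, pw, c0, d1x, 2.0 * d1y);
      step_ufdm(p2, q2, N, plo, pw, c0, d2x, 2.0 * d2y);
    }
    std::swap(p1, q1);
    std::swap(p2, q2);
  }
  return List::create(_["u1"] = NumericVector(p1, p1 + n),
                      _["u2"] = NumericVector(p2, p2 + n));
}
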