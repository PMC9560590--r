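#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Successive over-relaxation solve of div(sigma grad V) = 0 on a regular
// grid with a 7-point stencil.  Face conductances use the harmonic mean of
// the adjacent voxel conductivities scaled by face area over spacing, and
// are precomputed once.  Voxels with fixed != 0 are Dirichlet (held at
// their value in vinit).  Convergence: max voxel-equation imbalance,
// normalised by the diagonal, below tol * vscale.
// [[Rcpp::export(name = ".sor_solve")]]
List sor_solve(NumericVector sigma, IntegerVector fixed, NumericVector vinit,
               IntegerVector dims, NumericVector spacing,
               double vscale, double tol, int max_iter, double omega) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  double ax = hy * hz / hx, ay = hx * hz / hy, az = hx * hy / hz;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  std::vector<double> V(vinit.begin(), vinit.end());
  std::vector<int> fix(fixed.begin(), fixed.end());

  auto hmean = [](double a, double b) { return 2.0 * a * b / (a + b); };

  // face conductances: wx[i] couples voxel i-sx and i, etc.
  std::vector<double> wx(n, 0.0), wy(n, 0.0), wz(n, 0.0);
  for (R_xlen_t i = sx; i < n; i++)
    wx[i] = hmean(sigma[i - sx], sigma[i]) * ax;
  for (R_xlen_t i = sy; i < n; i++)
    wy[i] = hmean(sigma[i - sy], sigma[i]) * ay;
  for (R_xlen_t i = sz; i < n; i++)
    wz[i] = hmean(sigma[i - sz], sigma[i]) * az;

  double resid = R_PosInf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; iter++) {
    double maxr = 0.0;
    for (int k = 1; k < nz - 1; k++)
      for (int j = 1; j < ny - 1; j++) {
        R_xlen_t idx = sz * k + sy * j + 1;
        for (int i = 1; i < nx - 1; i++, idx++) {
          if (fix[idx]) continue;
          double wxm = wx[idx], wxp = wx[idx + sx];
          double wym = wy[idx], wyp = wy[idx + sy];
          double wzm = wz[idx], wzp = wz[idx + sz];
          double wsum = wxm + wxp + wym + wyp + wzm + wzp;
          double num = wxm * V[idx - sx] + wxp * V[idx + sx] +
                       wym * V[idx - sy] + wyp * V[idx + sy] +
                       wzm * V[idx - sz] + wzp * V[idx + sz];
          double r = num / wsum - V[idx];
          if (std::fabs(r) > maxr) maxr = std::fabs(r);
          V[idx] += omega * r;
        }
      }
    resid = maxr;
    if (maxr < tol * vscale) break;
  }

  NumericVector out(V.begin(), V.end());
  out.attr("dim") = dims;
  return List::create(_["V"] = out,
                      _["iterations"] = iter,
                      _["residual"] = resid,
                      _["converged"] = resid < tol * vscale);
}
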