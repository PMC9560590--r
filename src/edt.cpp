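#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared distance transform (lower envelope of parabolas) with sample
// spacing h; f holds squared distances on input, d the transformed values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1; // only finite parabolas enter the envelope
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    double qh = q * h;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      double vh = v[k] * h;
      s = ((f[q] + qh * qh) - (f[v[k]] + vh * vh)) / (2 * qh - 2 * vh);
      if (s <= z[k]) k--; // safe: z[0] = -INF, so k stays >= 0
      else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite sample in this line
    for (int p = 0; p < n; p++) d[p] = INF;
    return;
  }
  k = 0;
  for (int p = 0; p < n; p++) {
    double ph = p * h;
    while (z[k + 1] < ph) k++;
    double diff = ph - v[k] * h;
    d[p] = diff * diff + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3-D mask: for every voxel, the
// distance (mm) to the nearest TRUE voxel centre, honouring anisotropic
// voxel spacing.  Felzenszwalb-Huttenlocher separable algorithm.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims,
                    NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; i++) { f[i] = g[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nx, hx);
      for (int i = 0; i < nx; i++) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; j++) { f[j] = g[base + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, ny, hy);
      for (int j = 0; j < ny; j++) g[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  R_xlen_t pz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; k++) { f[k] = g[base + k * pz]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, nz, hz);
      for (int k = 0; k < nz; k++) g[base + k * pz] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
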