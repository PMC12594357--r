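#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope passes along the three axes.

static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) to the nearest TRUE site voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector sites, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = sites.size();
  NumericVector out(n);
  double *D = REAL(out);
  const int *s = LOGICAL(sites);
  for (R_xlen_t t = 0; t < n; ++t) D[t] = s[t] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) D[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) D[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }

  out.attr("dim") = dims;
  return out;
}

// Nearest-site label per pore voxel: one exact EDT per site label, running
// minimum with strict improvement, labels visited in increasing order, so a
// tie keeps the smallest label.  0 outside the pore mask.
// [[Rcpp::export]]
IntegerVector nearest_label_cpp(IntegerVector site_labels, LogicalVector pore,
                                IntegerVector dims, int nlab) {
  R_xlen_t n = site_labels.size();
  const int *sl = INTEGER(site_labels);
  const int *p = LOGICAL(pore);

  std::vector<double> best(n, INF);
  IntegerVector out(n, 0);
  int *o = INTEGER(out);
  LogicalVector mask(n);
  int *m = LOGICAL(mask);

  for (int b = 1; b <= nlab; ++b) {
    bool any = false;
    for (R_xlen_t t = 0; t < n; ++t) {
      m[t] = (sl[t] == b);
      if (m[t]) any = true;
    }
    if (!any) continue;
    NumericVector d2 = edt_sq_cpp(mask, dims);
    const double *D = REAL(d2);
    for (R_xlen_t t = 0; t < n; ++t) {
      if (!p[t]) continue;
      if (D[t] < best[t]) { best[t] = D[t]; o[t] = b; }
    }
  }
  out.attr("dim") = dims;
  return out;
}
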