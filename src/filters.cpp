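#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// Box median filter with truncated borders.
// [[Rcpp::export]]
NumericVector median3d_cpp(NumericVector x, IntegerVector dims, int radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(x.size());
  const double *in = REAL(x);
  double *o = REAL(out);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -radius; dk <= radius; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= nz) continue;
          for (int dj = -radius; dj <= radius; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= ny) continue;
            for (int di = -radius; di <= radius; ++di) {
              int ii = i + di; if (ii < 0 || ii >= nx) continue;
              buf.push_back(in[lin3(ii, jj, kk, nx, ny)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = 0.5 * (med + lo);
        }
        o[lin3(i, j, k, nx, ny)] = med;
      }
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian smoothing, reflective boundary, kernel radius ceil(3*sigma).
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector x, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += ker[t + r]; }
  for (int t = 0; t <= 2 * r; ++t) ker[t] /= s;

  NumericVector cur = clone(x);
  NumericVector nxt(x.size());
  const int dsz[3] = {nx, ny, nz};

  for (int axis = 0; axis < 3; ++axis) {
    double *a = REAL(cur), *b = REAL(nxt);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0;
          int c = (axis == 0) ? i : (axis == 1) ? j : k;
          int n = dsz[axis];
          for (int t = -r; t <= r; ++t) {
            int cc = c + t;
            if (cc < 0) cc = -cc - 1;            // reflect
            if (cc >= n) cc = 2 * n - cc - 1;
            if (cc < 0) cc = 0;                  // tiny-axis guard
            if (cc >= n) cc = n - 1;
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii = cc; else if (axis == 1) jj = cc; else kk = cc;
            acc += ker[t + r] * a[lin3(ii, jj, kk, nx, ny)];
          }
          b[lin3(i, j, k, nx, ny)] = acc;
        }
    std::swap(cur, nxt);
  }
  cur.attr("dim") = dims;
  return cur;
}

// Explicit finite-difference diffusion on the pore voxels (unit voxel volume,
// 6-adjacent exchange k*(c_j - c_i) per face and step, no-flux walls).
// Caller guarantees k <= 1/6 by sub-stepping.
// [[Rcpp::export]]
NumericVector voxel_diffuse_cpp(NumericVector mass, LogicalVector pore,
                                IntegerVector dims, double kcoef, int nsteps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = mass.size();
  const int *p = LOGICAL(pore);
  NumericVector cur = clone(mass);
  NumericVector nxt(n);

  for (int step = 0; step < nsteps; ++step) {
    double *a = REAL(cur), *b = REAL(nxt);
    std::copy(a, a + n, b);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t t = lin3(i, j, k, nx, ny);
          if (!p[t]) continue;
          if (i + 1 < nx) {
            R_xlen_t u = t + 1;
            if (p[u]) { double f = kcoef * (a[u] - a[t]); b[t] += f; b[u] -= f; }
          }
          if (j + 1 < ny) {
            R_xlen_t u = t + nx;
            if (p[u]) { double f = kcoef * (a[u] - a[t]); b[t] += f; b[u] -= f; }
          }
          if (k + 1 < nz) {
            R_xlen_t u = t + (R_xlen_t)nx * ny;
            if (p[u]) { double f = kcoef * (a[u] - a[t]); b[t] += f; b[u] -= f; }
          }
        }
    std::swap(cur, nxt);
  }
  cur.attr("dim") = dims;
  return cur;
}
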