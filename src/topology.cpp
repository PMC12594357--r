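#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel grids are R logical arrays, column-major, dims (nx, ny, nz), i fastest.
// All C++ indices are 0-based; R wrappers convert.

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

static inline bool at(const int *g, int i, int j, int k, int nx, int ny, int nz) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
  return g[lin(i, j, k, nx, ny)] != 0;
}

// Euler characteristic of the cubical complex spanned by the occupied voxels
// (union of closed unit cubes): chi = V - E + F - C.  For a 26-connected
// object this equals #components - #tunnels + #cavities.
// [[Rcpp::export]]
double chi_cpp(LogicalVector grid, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *g = LOGICAL(grid);
  long long V = 0, E = 0, F = 0, C = 0;

  // vertices: lattice points (a,b,c), incident voxels (a-1..a, b-1..b, c-1..c)
  for (int c = 0; c <= nz; ++c)
    for (int b = 0; b <= ny; ++b)
      for (int a = 0; a <= nx; ++a) {
        bool occ = false;
        for (int dk = -1; dk <= 0 && !occ; ++dk)
          for (int dj = -1; dj <= 0 && !occ; ++dj)
            for (int di = -1; di <= 0 && !occ; ++di)
              occ = at(g, a + di, b + dj, c + dk, nx, ny, nz);
        if (occ) ++V;
      }
  // edges along x: (a..a+1, b, c), incident voxels (a, b-1..b, c-1..c); cyclic for y, z
  for (int c = 0; c <= nz; ++c)
    for (int b = 0; b <= ny; ++b)
      for (int a = 0; a < nx; ++a) {
        bool occ = false;
        for (int dk = -1; dk <= 0 && !occ; ++dk)
          for (int dj = -1; dj <= 0 && !occ; ++dj)
            occ = at(g, a, b + dj, c + dk, nx, ny, nz);
        if (occ) ++E;
      }
  for (int c = 0; c <= nz; ++c)
    for (int b = 0; b < ny; ++b)
      for (int a = 0; a <= nx; ++a) {
        bool occ = false;
        for (int dk = -1; dk <= 0 && !occ; ++dk)
          for (int di = -1; di <= 0 && !occ; ++di)
            occ = at(g, a + di, b, c + dk, nx, ny, nz);
        if (occ) ++E;
      }
  for (int c = 0; c < nz; ++c)
    for (int b = 0; b <= ny; ++b)
      for (int a = 0; a <= nx; ++a) {
        bool occ = false;
        for (int dj = -1; dj <= 0 && !occ; ++dj)
          for (int di = -1; di <= 0 && !occ; ++di)
            occ = at(g, a + di, b + dj, c, nx, ny, nz);
        if (occ) ++E;
      }
  // faces normal to x: incident voxels (a-1..a, b, c); cyclic
  for (int c = 0; c < nz; ++c)
    for (int b = 0; b < ny; ++b)
      for (int a = 0; a <= nx; ++a)
        if (at(g, a - 1, b, c, nx, ny, nz) || at(g, a, b, c, nx, ny, nz)) ++F;
  for (int c = 0; c < nz; ++c)
    for (int b = 0; b <= ny; ++b)
      for (int a = 0; a < nx; ++a)
        if (at(g, a, b - 1, c, nx, ny, nz) || at(g, a, b, c, nx, ny, nz)) ++F;
  for (int c = 0; c <= nz; ++c)
    for (int b = 0; b < ny; ++b)
      for (int a = 0; a < nx; ++a)
        if (at(g, a, b, c - 1, nx, ny, nz) || at(g, a, b, c, nx, ny, nz)) ++F;

  R_xlen_t n = grid.size();
  for (R_xlen_t t = 0; t < n; ++t) if (g[t]) ++C;

  return (double)(V - E + F - C);
}

// Connected-component labelling (6 or 26 connectivity).  Labels are assigned
// in lexicographic (i,j,k) scan order of each component's first voxel, so
// label order equals the order of the components' lexicographically minimal
// voxels.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector grid, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *g = LOGICAL(grid);
  R_xlen_t n = grid.size();
  IntegerVector lab(n, 0);
  int *L = INTEGER(lab);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        R_xlen_t t0 = lin(i, j, k, nx, ny);
        if (!g[t0] || L[t0]) continue;
        ++next;
        L[t0] = next;
        stack.clear();
        stack.push_back(t0);
        while (!stack.empty()) {
          R_xlen_t t = stack.back(); stack.pop_back();
          int ci = (int)(t % nx), cj = (int)((t / nx) % ny), ck = (int)(t / ((R_xlen_t)nx * ny));
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                if (connectivity == 6 && (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1) continue;
                int ni = ci + di, nj = cj + dj, nk = ck + dk;
                if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz) continue;
                R_xlen_t tn = lin(ni, nj, nk, nx, ny);
                if (g[tn] && !L[tn]) { L[tn] = next; stack.push_back(tn); }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Components of equal nonzero integer labels (used to split a nearest-branch
// assignment into connected regions).  New labels in lexicographic scan order.
// [[Rcpp::export]]
IntegerVector label_components_eq_cpp(IntegerVector labels, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *g = INTEGER(labels);
  R_xlen_t n = labels.size();
  IntegerVector lab(n, 0);
  int *L = INTEGER(lab);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        R_xlen_t t0 = lin(i, j, k, nx, ny);
        if (g[t0] == 0 || L[t0]) continue;
        int val = g[t0];
        ++next;
        L[t0] = next;
        stack.clear();
        stack.push_back(t0);
        while (!stack.empty()) {
          R_xlen_t t = stack.back(); stack.pop_back();
          int ci = (int)(t % nx), cj = (int)((t / nx) % ny), ck = (int)(t / ((R_xlen_t)nx * ny));
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                if (connectivity == 6 && (std::abs(di) + std::abs(dj) + std::abs(dk)) != 1) continue;
                int ni = ci + di, nj = cj + dj, nk = ck + dk;
                if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz) continue;
                R_xlen_t tn = lin(ni, nj, nk, nx, ny);
                if (g[tn] == val && !L[tn]) { L[tn] = next; stack.push_back(tn); }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// --- local deletability machinery ------------------------------------------

// Number of 26-connected components of the 26 neighbours (centre excluded).
static int ncomp26_neighbours(const bool blk[27]) {
  // blk layout: index = (di+1) + 3*(dj+1) + 9*(dk+1); centre = 13
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !blk[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int t = stack[--top];
      int ti = t % 3, tj = (t / 3) % 3, tk = t / 9;
      for (int u = 0; u < 27; ++u) {
        if (u == 13 || u == t || !blk[u] || seen[u]) continue;
        int ui = u % 3, uj = (u / 3) % 3, uk = u / 9;
        if (std::abs(ui - ti) <= 1 && std::abs(uj - tj) <= 1 && std::abs(uk - tk) <= 1) {
          seen[u] = true;
          stack[top++] = u;
        }
      }
    }
  }
  return ncomp;
}

static inline bool blk_at(const bool blk[27], int di, int dj, int dk) {
  if (di < -1 || di > 1 || dj < -1 || dj > 1 || dk < -1 || dk > 1) return false;
  return blk[(di + 1) + 3 * (dj + 1) + 9 * (dk + 1)];
}

// chi(with centre) - chi(without centre).  Only cells incident to the centre
// cube change, so this local difference equals the global difference exactly.
static int delta_chi(const bool blk[27]) {
  // vertices of the centre cube at (di,dj,dk) in {0,1}^3 (offsets of the
  // low corner); covered by any other voxel in the 2x2x2 block of offsets
  // {di-1,di} x {dj-1,dj} x {dk-1,dk} minus the centre itself.
  int vhat = 0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        bool cov = false;
        for (int ck = dk - 1; ck <= dk && !cov; ++ck)
          for (int cj = dj - 1; cj <= dj && !cov; ++cj)
            for (int ci = di - 1; ci <= di && !cov; ++ci) {
              if (ci == 0 && cj == 0 && ck == 0) continue;
              cov = blk_at(blk, ci, cj, ck);
            }
        if (cov) ++vhat;
      }
  // 12 edges of the centre cube: 4 per axis direction; an x-edge at corner
  // (jy,jz) in {0,1}^2 is covered by voxels with di=0, dj in {jy-1,jy},
  // dk in {jz-1,jz}, excluding the centre.
  int ehat = 0;
  for (int axis = 0; axis < 3; ++axis)
    for (int b = 0; b <= 1; ++b)
      for (int c = 0; c <= 1; ++c) {
        bool cov = false;
        for (int db = b - 1; db <= b && !cov; ++db)
          for (int dc = c - 1; dc <= c && !cov; ++dc) {
            if (db == 0 && dc == 0) continue;
            int di = 0, dj = 0, dk = 0;
            if (axis == 0) { dj = db; dk = dc; }
            else if (axis == 1) { di = db; dk = dc; }
            else { di = db; dj = dc; }
            cov = blk_at(blk, di, dj, dk);
          }
        if (cov) ++ehat;
      }
  // 6 faces: each covered only by the respective face neighbour.
  int fhat = 0;
  const int fo[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int f = 0; f < 6; ++f)
    if (blk_at(blk, fo[f][0], fo[f][1], fo[f][2])) ++fhat;

  return (8 - vhat) - (12 - ehat) + (6 - fhat) - 1;
}

static void fill_block(const int *g, int i, int j, int k, int nx, int ny, int nz, bool blk[27]) {
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        blk[(di + 1) + 3 * (dj + 1) + 9 * (dk + 1)] =
          at(g, i + di, j + dj, k + dk, nx, ny, nz);
}

// Deletability of a pore voxel during homotopic thinning:
//  (i)   lies on the boundary (some 26-neighbour is background; the array
//        border counts as background),
//  (ii)  is not an ending point (has >= 2 neighbours; isolated voxels are
//        never deleted either),
//  (iii) removal keeps the Euler characteristic (evaluated locally, which is
//        exact), and
//  (iv)  removal keeps the number of 26-connected components (neighbourhood
//        test: the 26-neighbours form a single 26-component).
static bool deletable(const int *g, int i, int j, int k, int nx, int ny, int nz) {
  bool blk[27];
  fill_block(g, i, j, k, nx, ny, nz, blk);
  int nnb = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && blk[s]) ++nnb;
  if (nnb < 2) return false;                      // ending or isolated
  if (nnb == 26 && i > 0 && j > 0 && k > 0 &&
      i < nx - 1 && j < ny - 1 && k < nz - 1) return false; // interior, not on B
  if (ncomp26_neighbours(blk) != 1) return false; // component count would change
  if (delta_chi(blk) != 0) return false;          // Euler characteristic would change
  return true;
}

// Topology-only part of the test: removal preserves the local Euler
// characteristic and the neighbours form a single 26-component (no ending-
// point protection; isolated voxels still refused).
// [[Rcpp::export]]
bool is_simple_cpp(LogicalVector grid, IntegerVector dims, int i, int j, int k) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *g = LOGICAL(grid);
  if (!at(g, i, j, k, nx, ny, nz)) stop("voxel is not in the pore set");
  bool blk[27];
  fill_block(g, i, j, k, nx, ny, nz, blk);
  int nnb = 0;
  for (int s = 0; s < 27; ++s) if (s != 13 && blk[s]) ++nnb;
  if (nnb == 0) return false;
  if (ncomp26_neighbours(blk) != 1) return false;
  return delta_chi(blk) == 0;
}

// [[Rcpp::export]]
bool is_deletable_cpp(LogicalVector grid, IntegerVector dims, int i, int j, int k) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *g = LOGICAL(grid);
  if (!at(g, i, j, k, nx, ny, nz)) stop("voxel is not in the pore set");
  return deletable(g, i, j, k, nx, ny, nz);
}

// Homotopic thinning to the fixed point.  Each pass collects the current
// boundary voxels, orders them by ascending 26-neighbour count at pass start
// with lexicographic (i,j,k) tie-break, and attempts deletion sequentially
// against the already-updated volume.  Deleting the most weakly connected
// voxels first removes would-be spur seeds before ending-point protection
// can freeze them, which yields clean closed curves on tori and clean paths
// on tubes; the fixed order keeps results reproducible bit-for-bit.
// [[Rcpp::export]]
LogicalVector thin_cpp(LogicalVector grid, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out = clone(grid);
  int *g = LOGICAL(out);
  std::vector<std::pair<int, R_xlen_t> > cand; // (neighbour count, index)
  std::vector<R_xlen_t> order_idx;

  bool changed = true;
  while (changed) {
    changed = false;
    cand.clear();
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j)
        for (int k = 0; k < nz; ++k) {
          R_xlen_t t = lin(i, j, k, nx, ny);
          if (!g[t]) continue;
          bool onB = false;
          int nn = 0;
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (di == 0 && dj == 0 && dk == 0) continue;
                if (at(g, i + di, j + dj, k + dk, nx, ny, nz)) ++nn;
                else onB = true;
              }
          if (onB) cand.push_back(std::make_pair(nn, t));
        }
    // enumeration above is lexicographic in (i,j,k); a stable sort by the
    // neighbour count therefore breaks ties lexicographically
    std::stable_sort(cand.begin(), cand.end(),
                     [](const std::pair<int, R_xlen_t> &a,
                        const std::pair<int, R_xlen_t> &b) { return a.first < b.first; });
    for (size_t c = 0; c < cand.size(); ++c) {
      R_xlen_t t = cand[c].second;
      if (!g[t]) continue;
      int i = (int)(t % nx), j = (int)((t / nx) % ny), k = (int)(t / ((R_xlen_t)nx * ny));
      if (deletable(g, i, j, k, nx, ny, nz)) {
        g[t] = 0;
        changed = true;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// 26-neighbour count inside a mask, per voxel (0 outside the mask).
// [[Rcpp::export]]
IntegerVector neighbour_count_cpp(LogicalVector grid, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *g = LOGICAL(grid);
  IntegerVector out(grid.size(), 0);
  int *o = INTEGER(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = lin(i, j, k, nx, ny);
        if (!g[t]) continue;
        int nn = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (at(g, i + di, j + dj, k + dk, nx, ny, nz)) ++nn;
            }
        o[t] = nn;
      }
  out.attr("dim") = dims;
  return out;
}
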