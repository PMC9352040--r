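// Voxel kernels for 3D canal-network morphometry.
//
// Array layout matches R: column-major with dim = (nz, ny, nx), so the
// z (slice) index varies fastest.  All distances are physical (micrometres)
// with per-axis spacing (dz, dy, dx).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double DINF = 1e300;

// ---------------------------------------------------------------------------
// 1D squared-distance transform (lower envelope of parabolas), anisotropic.
// f: input squared distances at positions i*w; d: output.  Entries >= DINF
// are treated as "no source here".
// ---------------------------------------------------------------------------
static void dt1d(const double* f, double* d, int n, double w,
                 int* v, double* z) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] >= DINF) continue;
    double xq = q * w;
    double fq = f[q] + xq * xq;
    double s = 0.0;
    while (k >= 0) {
      double xp = v[k] * w;
      s = (fq - (f[v[k]] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -DINF : s;
    z[k + 1] = DINF;
  }
  if (k < 0) {                    // no finite source on this line
    for (int i = 0; i < n; ++i) d[i] = DINF;
    return;
  }
  int j = 0;
  for (int i = 0; i < n; ++i) {
    double xi = i * w;
    while (z[j + 1] < xi) ++j;
    double xv = v[j] * w;
    d[i] = (xi - xv) * (xi - xv) + f[v[j]];
  }
}

// Apply dt1d along one axis of the (nz, ny, nx) grid.
static void dt_axis(std::vector<double>& D, int nz, int ny, int nx,
                    int axis, double w) {
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  if (axis == 0) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        std::size_t base = (std::size_t)nz * (y + (std::size_t)ny * x);
        for (int i = 0; i < n; ++i) f[i] = D[base + i];
        dt1d(f.data(), d.data(), n, w, v.data(), z.data());
        for (int i = 0; i < n; ++i) D[base + i] = d[i];
      }
  } else if (axis == 1) {
    for (int x = 0; x < nx; ++x)
      for (int zz = 0; zz < nz; ++zz) {
        std::size_t base = zz + (std::size_t)nz * (std::size_t)ny * x;
        for (int i = 0; i < n; ++i) f[i] = D[base + (std::size_t)nz * i];
        dt1d(f.data(), d.data(), n, w, v.data(), z.data());
        for (int i = 0; i < n; ++i) D[base + (std::size_t)nz * i] = d[i];
      }
  } else {
    std::size_t stride = (std::size_t)nz * ny;
    for (int y = 0; y < ny; ++y)
      for (int zz = 0; zz < nz; ++zz) {
        std::size_t base = zz + (std::size_t)nz * y;
        for (int i = 0; i < n; ++i) f[i] = D[base + stride * i];
        dt1d(f.data(), d.data(), n, w, v.data(), z.data());
        for (int i = 0; i < n; ++i) D[base + stride * i] = d[i];
      }
  }
}

// Squared EDT to the source set (sources have value 0).  If outside_bg,
// every position outside the grid also counts as a source; its contribution
// is the straight-line distance to the nearest face, which is exact because
// the nearest outside voxel centre lies along a single axis.
static void edt_sq_core(std::vector<double>& D, int nz, int ny, int nx,
                        double wz, double wy, double wx, bool outside_bg) {
  dt_axis(D, nz, ny, nx, 0, wz);
  dt_axis(D, nz, ny, nx, 1, wy);
  dt_axis(D, nz, ny, nx, 2, wx);
  if (outside_bg) {
    std::size_t i = 0;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int zz = 0; zz < nz; ++zz, ++i) {
          double bz = (double)std::min(zz + 1, nz - zz) * wz;
          double by = (double)std::min(y + 1, ny - y) * wy;
          double bx = (double)std::min(x + 1, nx - x) * wx;
          double b = std::min(bz, std::min(by, bx));
          if (b * b < D[i]) D[i] = b * b;
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dims,
                         NumericVector spacing, bool outside_bg) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::size_t N = (std::size_t)nz * ny * nx;
  std::vector<double> D(N);
  for (std::size_t i = 0; i < N; ++i) D[i] = fg[i] ? DINF : 0.0;
  edt_sq_core(D, nz, ny, nx, spacing[0], spacing[1], spacing[2], outside_bg);
  NumericVector out(N);
  for (std::size_t i = 0; i < N; ++i) out[i] = D[i];
  return out;
}

// ---------------------------------------------------------------------------
// Local thickness: LT(v) = max{ r(c) : ||v - c|| <= r(c) + h, c foreground },
// where r(c) = EDT(c) - h is the inscribed-sphere radius at c and
// h = min(spacing)/2 (radius measured to the voxel boundary; a sphere
// "contains" a voxel when it reaches within half a voxel of its centre).
// Processed by descending radius level: v is covered at level r iff its
// distance to { c : r(c) >= r } is <= r + h.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector fg, IntegerVector dims,
                                  NumericVector spacing, int max_levels) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::size_t N = (std::size_t)nz * ny * nx;
  double wz = spacing[0], wy = spacing[1], wx = spacing[2];
  double hmin = 0.5 * std::min(wz, std::min(wy, wx));

  std::vector<double> D(N);
  for (std::size_t i = 0; i < N; ++i) D[i] = fg[i] ? DINF : 0.0;
  edt_sq_core(D, nz, ny, nx, wz, wy, wx, true);

  std::vector<double> rad(N, 0.0);
  std::vector<double> levels;
  for (std::size_t i = 0; i < N; ++i) {
    if (fg[i]) {
      rad[i] = std::sqrt(D[i]) - hmin;
      levels.push_back(rad[i]);
    }
  }
  NumericVector out(N);
  if (levels.empty()) return out;

  std::sort(levels.begin(), levels.end(), std::greater<double>());
  std::vector<double> uniq;
  for (double r : levels)
    if (uniq.empty() || uniq.back() - r > 1e-9) uniq.push_back(r);
  if ((int)uniq.size() > max_levels) {      // thin the ladder, keep extremes
    std::vector<double> keep;
    double step = (double)(uniq.size() - 1) / (max_levels - 1);
    for (int k = 0; k < max_levels; ++k)
      keep.push_back(uniq[(std::size_t)std::llround(k * step)]);
    uniq = keep;
  }

  std::vector<double> lt(N, 0.0), E(N);
  for (double r : uniq) {
    for (std::size_t i = 0; i < N; ++i)
      E[i] = (fg[i] && rad[i] >= r - 1e-9) ? 0.0 : DINF;
    edt_sq_core(E, nz, ny, nx, wz, wy, wx, false);
    double r2 = (r + hmin) * (r + hmin) * (1.0 + 1e-12) + 1e-9;
    for (std::size_t i = 0; i < N; ++i)
      if (fg[i] && lt[i] == 0.0 && E[i] <= r2) lt[i] = r;
  }
  for (std::size_t i = 0; i < N; ++i) {
    if (fg[i] && lt[i] == 0.0) lt[i] = rad[i];
    out[i] = lt[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, zero outside the grid.
// ---------------------------------------------------------------------------
static void blur_axis(std::vector<double>& A, int nz, int ny, int nx,
                      int axis, const std::vector<double>& k) {
  int h = (int)(k.size() - 1) / 2;
  int n = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  std::size_t stride = (axis == 0) ? 1 :
                       (axis == 1) ? (std::size_t)nz : (std::size_t)nz * ny;
  std::vector<double> line(n), outl(n);
  int n1 = (axis == 0) ? ny : nz;
  int n2 = (axis == 2) ? ny : nx;
  std::size_t s1 = (axis == 0) ? (std::size_t)nz : 1;
  std::size_t s2 = (axis == 2) ? (std::size_t)nz : (std::size_t)nz * ny;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      std::size_t base = s1 * a + s2 * b;
      for (int i = 0; i < n; ++i) line[i] = A[base + stride * i];
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = -h; j <= h; ++j) {
          int p = i + j;
          if (p >= 0 && p < n) s += k[j + h] * line[p];
        }
        outl[i] = s;
      }
      for (int i = 0; i < n; ++i) A[base + stride * i] = outl[i];
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims,
                          double sigma, int ksize) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::size_t N = (std::size_t)nz * ny * nx;
  int h = (ksize - 1) / 2;
  std::vector<double> k(ksize);
  double s = 0.0;
  for (int j = -h; j <= h; ++j) {
    k[j + h] = std::exp(-0.5 * j * j / (sigma * sigma));
    s += k[j + h];
  }
  for (double& v : k) v /= s;
  std::vector<double> A(N);
  for (std::size_t i = 0; i < N; ++i) A[i] = vol[i];
  blur_axis(A, nz, ny, nx, 0, k);
  blur_axis(A, nz, ny, nx, 1, k);
  blur_axis(A, nz, ny, nx, 2, k);
  NumericVector out(N);
  for (std::size_t i = 0; i < N; ++i) out[i] = A[i];
  return out;
}

// ---------------------------------------------------------------------------
// Connected components with 6/18/26 connectivity.  Labels are assigned in
// scan order; size ranking happens on the R side.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_cc(LogicalVector fg, IntegerVector dims,
                           int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::size_t N = (std::size_t)nz * ny * nx;
  std::vector<int> off_z, off_y, off_x;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        bool ok = (connectivity == 26) ||
                  (connectivity == 18 && m <= 2) ||
                  (connectivity == 6 && m == 1);
        if (ok) { off_z.push_back(dz); off_y.push_back(dy); off_x.push_back(dx); }
      }
  int no = (int)off_z.size();
  IntegerVector lab(N);
  std::vector<std::size_t> stack;
  int next = 0;
  for (std::size_t i = 0; i < N; ++i) {
    if (!fg[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      std::size_t c = stack.back(); stack.pop_back();
      int zz = (int)(c % nz);
      int yy = (int)((c / nz) % ny);
      int xx = (int)(c / ((std::size_t)nz * ny));
      for (int o = 0; o < no; ++o) {
        int z2 = zz + off_z[o], y2 = yy + off_y[o], x2 = xx + off_x[o];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        std::size_t j = z2 + (std::size_t)nz * (y2 + (std::size_t)ny * x2);
        if (fg[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Homotopy-preserving thinning.
//
// A border voxel is deleted only if it is a (26,6) simple point (deletion
// keeps both foreground 26-topology and background 6-topology) and is not a
// curve endpoint (<= 1 foreground 26-neighbour).  Deletion is sequential
// within each of six directional sub-iterations with simplicity re-checked
// at deletion time, which guarantees homotopy equivalence; the fixed scan
// order makes the result deterministic.
// ---------------------------------------------------------------------------

// neighbourhood flags: index (dz+1) + 3*((dy+1) + 3*(dx+1)); centre = 13.
static inline int nb_index(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

static void gather_nb(const std::vector<uint8_t>& img, int nz, int ny, int nx,
                      int zz, int yy, int xx, uint8_t* nb) {
  int q = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz, ++q) {
        int z2 = zz + dz, y2 = yy + dy, x2 = xx + dx;
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          nb[q] = 0;
        else
          nb[q] = img[z2 + (std::size_t)nz * (y2 + (std::size_t)ny * x2)];
      }
  // q runs dx slowest / dz fastest; recompute into canonical order
  // (the loop above already matches nb_index: dz fastest)
}

static int nb26_count(const uint8_t* nb) {
  int c = 0;
  for (int q = 0; q < 27; ++q)
    if (q != 13 && nb[q]) ++c;
  return c;
}

// offsets of the 27 cells
static const int CELL_D[27][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
}; // [q] = {dz, dy, dx} with q = (dz+1) + 3*((dy+1) + 3*(dx+1))

static bool is_simple(const uint8_t* nb) {
  // Condition 1: exactly one 26-component of foreground among the 26 cells.
  int seen[27] = {0};
  int comps = 0;
  int stack[27];
  for (int q = 0; q < 27; ++q) {
    if (q == 13 || !nb[q] || seen[q]) continue;
    if (++comps > 1) return false;
    int top = 0;
    stack[top++] = q;
    seen[q] = 1;
    while (top > 0) {
      int c = stack[--top];
      for (int p = 0; p < 27; ++p) {
        if (p == 13 || p == c || !nb[p] || seen[p]) continue;
        if (std::abs(CELL_D[p][0] - CELL_D[c][0]) <= 1 &&
            std::abs(CELL_D[p][1] - CELL_D[c][1]) <= 1 &&
            std::abs(CELL_D[p][2] - CELL_D[c][2]) <= 1) {
          seen[p] = 1;
          stack[top++] = p;
        }
      }
    }
  }
  if (comps != 1) return false;

  // Condition 2: exactly one 6-component of background within the
  // 18-neighbourhood that touches a face neighbour of the centre.
  int seenb[27] = {0};
  comps = 0;
  for (int q = 0; q < 27; ++q) {
    int m = std::abs(CELL_D[q][0]) + std::abs(CELL_D[q][1]) + std::abs(CELL_D[q][2]);
    if (m != 1 || nb[q] || seenb[q]) continue;   // start only from face cells
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = q;
    seenb[q] = 1;
    while (top > 0) {
      int c = stack[--top];
      for (int p = 0; p < 27; ++p) {
        if (p == 13 || nb[p] || seenb[p]) continue;
        int mp = std::abs(CELL_D[p][0]) + std::abs(CELL_D[p][1]) + std::abs(CELL_D[p][2]);
        if (mp > 2) continue;                     // stay inside N18
        int dd = std::abs(CELL_D[p][0] - CELL_D[c][0]) +
                 std::abs(CELL_D[p][1] - CELL_D[c][1]) +
                 std::abs(CELL_D[p][2] - CELL_D[c][2]);
        if (dd == 1) { seenb[p] = 1; stack[top++] = p; }
      }
    }
  }
  return comps == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::size_t N = (std::size_t)nz * ny * nx;
  std::vector<uint8_t> img(N);
  for (std::size_t i = 0; i < N; ++i) img[i] = mask[i] ? 1 : 0;

  const int dir[6][3] = {           // {dz, dy, dx}: U, D, N, S, E, W order
    {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}
  };
  uint8_t nb[27];
  std::vector<std::size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      std::size_t i = 0;
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int zz = 0; zz < nz; ++zz, ++i) {
            if (!img[i]) continue;
            int z2 = zz + dir[d][0], y2 = y + dir[d][1], x2 = x + dir[d][2];
            bool border;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
              border = true;
            else
              border = !img[z2 + (std::size_t)nz * (y2 + (std::size_t)ny * x2)];
            if (!border) continue;
            gather_nb(img, nz, ny, nx, zz, y, x, nb);
            if (nb26_count(nb) <= 1) continue;   // endpoint (or isolated)
            if (is_simple(nb)) cand.push_back(i);
          }
      for (std::size_t c : cand) {
        if (!img[c]) continue;
        int zz = (int)(c % nz);
        int yy = (int)((c / nz) % ny);
        int xx = (int)(c / ((std::size_t)nz * ny));
        gather_nb(img, nz, ny, nx, zz, yy, xx, nb);
        if (nb26_count(nb) <= 1) continue;
        if (is_simple(nb)) { img[c] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(N);
  for (std::size_t i = 0; i < N; ++i) out[i] = img[i] != 0;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::size_t N = (std::size_t)nz * ny * nx;
  IntegerVector out(N);
  std::size_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int zz = 0; zz < nz; ++zz, ++i) {
        if (!mask[i]) { out[i] = 0; continue; }
        int c = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (dz == 0 && dy == 0 && dx == 0) continue;
              int z2 = zz + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                  x2 < 0 || x2 >= nx) continue;
              if (mask[z2 + (std::size_t)nz * (y2 + (std::size_t)ny * x2)]) ++c;
            }
        out[i] = c;
      }
  return out;
}

// 26-adjacency edges among TRUE voxels, as 1-based linear index pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_adjacency26(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> from, to;
  // 13 forward offsets (lexicographically positive in (dx, dy, dz))
  std::vector<int> oz, oy, ox;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx > 0 || (dx == 0 && dy > 0) || (dx == 0 && dy == 0 && dz > 0)) {
          oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
        }
      }
  std::size_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int zz = 0; zz < nz; ++zz, ++i) {
        if (!mask[i]) continue;
        for (std::size_t o = 0; o < oz.size(); ++o) {
          int z2 = zz + oz[o], y2 = y + oy[o], x2 = x + ox[o];
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
              x2 < 0 || x2 >= nx) continue;
          std::size_t j = z2 + (std::size_t)nz * (y2 + (std::size_t)ny * x2);
          if (mask[j]) { from.push_back((int)i + 1); to.push_back((int)j + 1); }
        }
      }
  IntegerMatrix out((int)from.size(), 2);
  for (int r = 0; r < (int)from.size(); ++r) {
    out(r, 0) = from[r];
    out(r, 1) = to[r];
  }
  return out;
}
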