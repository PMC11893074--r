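#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Low-level raster kernels shared by the registration, localization and
// morphometry code. All matrices follow R's convention: rows = y (axial),
// columns = x (lateral). Coordinates are 0-based pixel indices; sampling
// outside the image clamps to the edge.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double catrom(double p0, double p1, double p2, double p3, double t) {
  // Catmull-Rom cubic: interpolates p1..p2, reproduces polynomials up to
  // degree 3 exactly (so linear ramps are preserved to machine precision).
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericMatrix cpp_bicubic_resize(NumericMatrix img, int factor) {
  int H = img.nrow(), W = img.ncol();
  int Ho = H * factor, Wo = W * factor;
  NumericMatrix out(Ho, Wo);
  // 2-pixel linearly extrapolated border so that boundary cells (and the
  // extrapolated tail past the last sample) still reproduce linear ramps.
  int He = H + 4, We = W + 4;
  std::vector<double> E(He * We);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      E[(r + 2) + (c + 2) * He] = img(r, c);
  for (int r = 2; r < H + 2; ++r) {
    double v0 = E[r + 2 * He], v1 = (W > 1) ? E[r + 3 * He] : v0;
    E[r + 1 * He] = 2 * v0 - v1;
    E[r + 0 * He] = 3 * v0 - 2 * v1;
    double w0 = E[r + (W + 1) * He], w1 = (W > 1) ? E[r + W * He] : w0;
    E[r + (W + 2) * He] = 2 * w0 - w1;
    E[r + (W + 3) * He] = 3 * w0 - 2 * w1;
  }
  for (int c = 0; c < We; ++c) {
    double v0 = E[2 + c * He], v1 = (H > 1) ? E[3 + c * He] : v0;
    E[1 + c * He] = 2 * v0 - v1;
    E[0 + c * He] = 3 * v0 - 2 * v1;
    double w0 = E[(H + 1) + c * He], w1 = (H > 1) ? E[H + c * He] : w0;
    E[(H + 2) + c * He] = 2 * w0 - w1;
    E[(H + 3) + c * He] = 3 * w0 - 2 * w1;
  }
  // corner-aligned: output index k samples input coordinate k / factor,
  // so out[k * factor] == img[k] exactly.
  std::vector<double> colv(4);
  for (int r = 0; r < Ho; ++r) {
    double y = (double)r / factor;
    int iy = (int)std::floor(y);
    double fy = y - iy;
    for (int c = 0; c < Wo; ++c) {
      double x = (double)c / factor;
      int ix = (int)std::floor(x);
      double fx = x - ix;
      for (int j = 0; j < 4; ++j) {
        int cc = (ix + 1 + j) * He;  // extended column index (ix - 1 + j) + 2
        int rr = iy + 1;             // extended row of (iy - 1) is iy + 1
        colv[j] = catrom(E[rr + cc], E[rr + 1 + cc], E[rr + 2 + cc],
                         E[rr + 3 + cc], fy);
      }
      out(r, c) = catrom(colv[0], colv[1], colv[2], colv[3], fx);
    }
  }
  return out;
}

static inline double bilinear(const NumericMatrix &img, double y, double x) {
  int H = img.nrow(), W = img.ncol();
  y = clampd(y, 0.0, H - 1.0);
  x = clampd(x, 0.0, W - 1.0);
  int iy = (int)std::floor(y), ix = (int)std::floor(x);
  if (iy == H - 1) iy = H - 2 < 0 ? 0 : H - 2;
  if (ix == W - 1) ix = W - 2 < 0 ? 0 : W - 2;
  double fy = y - iy, fx = x - ix;
  if (H == 1) { iy = 0; fy = 0.0; }
  if (W == 1) { ix = 0; fx = 0.0; }
  int iy2 = clampi(iy + 1, 0, H - 1), ix2 = clampi(ix + 1, 0, W - 1);
  return (1 - fy) * ((1 - fx) * img(iy, ix) + fx * img(iy, ix2)) +
         fy * ((1 - fx) * img(iy2, ix) + fx * img(iy2, ix2));
}

// out(r, c) = img(r + dy(r, c), c + dx(r, c)), displacements in pixels.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix dx, NumericMatrix dy) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      out(r, c) = bilinear(img, r + dy(r, c), c + dx(r, c));
  return out;
}

// Affine sampling about the image center: out(r, c) = img at
// (x, y) = A * (xc, yc) + t + center, with x = column, y = row.
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, double a11, double a12,
                              double a21, double a22, double tx, double ty) {
  int H = img.nrow(), W = img.ncol();
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    double yc = r - cy;
    for (int c = 0; c < W; ++c) {
      double xc = c - cx;
      double sx = a11 * xc + a12 * yc + tx + cx;
      double sy = a21 * xc + a22 * yc + ty + cy;
      out(r, c) = bilinear(img, sy, sx);
    }
  }
  return out;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance in pixels from each TRUE pixel to the nearest FALSE pixel.
// Pixels outside the image count as background (border-bounded vessels).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e20;
  z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask, bool pad_background = true) {
  int H = mask.nrow(), W = mask.ncol();
  // pad by one pixel on every side; with pad_background the image border
  // acts as background (a 0-distance source), otherwise as foreground.
  int Hp = H + 2, Wp = W + 2;
  std::vector<double> g(Hp * Wp, 0.0);
  const double INF = 1e18;
  for (int r = 0; r < Hp; ++r)
    for (int c = 0; c < Wp; ++c) {
      bool inside = (r > 0 && r <= H && c > 0 && c <= W);
      bool fg = inside ? (mask(r - 1, c - 1) == TRUE) : !pad_background;
      g[r + c * Hp] = fg ? INF : 0.0;
    }
  std::vector<double> f(std::max(Hp, Wp)), d(std::max(Hp, Wp));
  for (int c = 0; c < Wp; ++c) {
    for (int r = 0; r < Hp; ++r) f[r] = g[r + c * Hp];
    dt1d(f, d, Hp);
    for (int r = 0; r < Hp; ++r) g[r + c * Hp] = d[r];
  }
  for (int r = 0; r < Hp; ++r) {
    for (int c = 0; c < Wp; ++c) f[c] = g[r + c * Hp];
    dt1d(f, d, Wp);
    for (int c = 0; c < Wp; ++c) g[r + c * Hp] = d[c];
  }
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      out(r, c) = std::sqrt(g[(r + 1) + (c + 1) * Hp]);
  return out;
}

// Zhang-Suen morphological thinning to a 1-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<int> img(H * W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      img[r * W + c] = mask(r, c) ? 1 : 0;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img[r * W + c];
  };
  bool changed = true;
  std::vector<int> del;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c) {
          if (!img[r * W + c]) continue;
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
              p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(r * W + c);
        }
      if (!del.empty()) changed = true;
      for (size_t i = 0; i < del.size(); ++i) img[del[i]] = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      out(r, c) = img[r * W + c] == 1;
  return out;
}

// 8-connected component labelling (0 = background).
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r0 = 0; r0 < H; ++r0)
    for (int c0 = 0; c0 < W; ++c0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      q.push(std::make_pair(r0, c0));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            int r = p.first + dr, c = p.second + dc;
            if (r < 0 || r >= H || c < 0 || c >= W) continue;
            if (mask(r, c) && lab(r, c) == 0) {
              lab(r, c) = next;
              q.push(std::make_pair(r, c));
            }
          }
      }
    }
  return lab;
}

// Strict-or-tied local maxima of a 3x3 neighbourhood, value >= thresh.
// Returns a 3-column matrix (row, col, value), 1-based indices.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericMatrix img, double thresh) {
  int H = img.nrow(), W = img.ncol();
  std::vector<double> rows, cols, vals;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      double v = img(r, c);
      if (v < thresh) continue;
      bool ismax = true;
      for (int dr = -1; dr <= 1 && ismax; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (img(rr, cc) > v) { ismax = false; break; }
        }
      if (ismax) {
        rows.push_back(r + 1);
        cols.push_back(c + 1);
        vals.push_back(v);
      }
    }
  NumericMatrix out(rows.size(), 3);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
    out(i, 2) = vals[i];
  }
  return out;
}
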