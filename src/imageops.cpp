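#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Low-level raster primitives shared by the cilia and nuclei pipelines.
// All matrices are column-major (R layout); coordinates returned to R are
// 1-based (row, col).

// ---- connected components, 8-connectivity -------------------------------

// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// ---- Moore-neighbour boundary tracing -----------------------------------

// Ordered external boundary of component `id` in a label image.  Clockwise
// in (row, col) screen coordinates, Jacob's stopping criterion.

// [[Rcpp::export(name = ".trace_boundary")]]
IntegerMatrix trace_boundary(const IntegerMatrix& lab, const int id,
                             int r0 = -1, int c0 = -1) {
  const int nr = lab.nrow(), nc = lab.ncol();
  if (r0 < 0 || c0 < 0 || r0 >= nr || c0 >= nc || lab(r0, c0) != id) {
    r0 = -1; c0 = -1;
    for (int c = 0; c < nc && r0 < 0; ++c)
      for (int r = 0; r < nr; ++r)
        if (lab(r, c) == id) { r0 = r; c0 = c; break; }
    if (r0 < 0) return IntegerMatrix(0, 2);
  }

  // neighbour offsets, clockwise starting west
  const int dr[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
  const int dc[8] = {-1, -1,  0,  1,  1,  1, 0, -1};
  std::vector<int> rows, cols;
  rows.push_back(r0); cols.push_back(c0);

  int rcur = r0, ccur = c0;
  int backtrack = 0; // we scanned from the left, so we "came from" the west
  int first_dir = -1;
  const int guard_max = 8 * (nr * nc + 8);
  for (int guard = 0; guard < guard_max; ++guard) {
    int found = -1;
    for (int k = 0; k < 8; ++k) {
      int dir = (backtrack + 1 + k) % 8;
      int r2 = rcur + dr[dir], c2 = ccur + dc[dir];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (lab(r2, c2) == id) { found = dir; break; }
    }
    if (found < 0) break; // isolated pixel
    if (rcur == r0 && ccur == c0) {
      // Jacob's stopping criterion: leaving the start a second time in the
      // same direction as the first departure closes the boundary.
      if (first_dir < 0) first_dir = found;
      else if (found == first_dir) break;
    }
    rcur += dr[found];
    ccur += dc[found];
    if (!(rcur == r0 && ccur == c0)) { rows.push_back(rcur); cols.push_back(ccur); }
    backtrack = (found + 4) % 8;
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1; // 1-based row
    out(i, 1) = cols[i] + 1; // 1-based col
  }
  return out;
}

// ---- hole filling --------------------------------------------------------

// Foreground plus any background region not connected (4-conn) to the frame.

// [[Rcpp::export(name = ".fill_holes")]]
IntegerMatrix fill_holes(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix outside(nr, nc); // 1 = background reachable from border
  std::queue<int> q;
  for (int r = 0; r < nr; ++r) {
    for (int c : {0, nc - 1}) {
      if (mask(r, c) == 0 && outside(r, c) == 0) { outside(r, c) = 1; q.push(r + c * nr); }
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r : {0, nr - 1}) {
      if (mask(r, c) == 0 && outside(r, c) == 0) { outside(r, c) = 1; q.push(r + c * nr); }
    }
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) == 0 && outside(r2, c2) == 0) { outside(r2, c2) = 1; q.push(r2 + c2 * nr); }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = (mask(r, c) != 0 || outside(r, c) == 0) ? 1 : 0;
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_l2")]]
NumericMatrix edt_l2(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = mask(r, c) != 0 ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) { // along rows (within a column)
    for (int r = 0; r < nr; ++r) f[r] = d(r, c);
    dt1d(f, out, nr);
    for (int r = 0; r < nr; ++r) d(r, c) = out[r];
  }
  for (int r = 0; r < nr; ++r) { // along columns
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt1d(f, out, nc);
    for (int c = 0; c < nc; ++c) d(r, c) = out[c];
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = std::sqrt(d(r, c));
  return d;
}

// ---- hysteresis edge linking (Canny final step) --------------------------

// Keep weak edel pixels 8-connected (possibly transitively) to a strong one.

// [[Rcpp::export(name = ".hysteresis")]]
IntegerMatrix hysteresis(const IntegerMatrix& strong, const IntegerMatrix& weak) {
  const int nr = strong.nrow(), nc = strong.ncol();
  IntegerMatrix out(nr, nc);
  std::queue<int> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (strong(r, c) != 0) { out(r, c) = 1; q.push(r + c * nr); }
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        int r2 = r + dr, c2 = c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (weak(r2, c2) != 0 && out(r2, c2) == 0) { out(r2, c2) = 1; q.push(r2 + c2 * nr); }
      }
    }
  }
  return out;
}

// ---- CLAHE ---------------------------------------------------------------

// Contrast-limited adaptive histogram equalisation on an 8-bit image, with
// bilinear interpolation between per-tile mappings (OpenCV-style semantics:
// clip threshold = clip_limit * tile_area / 256, excess redistributed).

// [[Rcpp::export(name = ".clahe8")]]
IntegerMatrix clahe8(const IntegerMatrix& img, double clip_limit,
                     int tiles_r, int tiles_c) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nbins = 256;
  std::vector<std::vector<double>> lut(tiles_r * tiles_c,
                                       std::vector<double>(nbins, 0.0));
  std::vector<double> tile_cr(tiles_r), tile_cc(tiles_c);
  std::vector<int> r0(tiles_r), r1(tiles_r), c0(tiles_c), c1(tiles_c);
  for (int i = 0; i < tiles_r; ++i) {
    r0[i] = (int)std::floor(nr * (double)i / tiles_r);
    r1[i] = (int)std::floor(nr * (double)(i + 1) / tiles_r);
    tile_cr[i] = 0.5 * (r0[i] + r1[i] - 1);
  }
  for (int j = 0; j < tiles_c; ++j) {
    c0[j] = (int)std::floor(nc * (double)j / tiles_c);
    c1[j] = (int)std::floor(nc * (double)(j + 1) / tiles_c);
    tile_cc[j] = 0.5 * (c0[j] + c1[j] - 1);
  }
  for (int i = 0; i < tiles_r; ++i) {
    for (int j = 0; j < tiles_c; ++j) {
      std::vector<double> hist(nbins, 0.0);
      double area = (double)(r1[i] - r0[i]) * (c1[j] - c0[j]);
      for (int c = c0[j]; c < c1[j]; ++c)
        for (int r = r0[i]; r < r1[i]; ++r) {
          int v = img(r, c);
          if (v < 0) v = 0;
          if (v > 255) v = 255;
          hist[v] += 1.0;
        }
      double clip = std::max(1.0, clip_limit * area / nbins);
      double excess = 0.0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > clip) { excess += hist[b] - clip; hist[b] = clip; }
      double add = excess / nbins;
      for (int b = 0; b < nbins; ++b) hist[b] += add;
      double cdf = 0.0, scale = 255.0 / area;
      std::vector<double>& L = lut[i * tiles_c + j];
      for (int b = 0; b < nbins; ++b) {
        cdf += hist[b];
        L[b] = std::round(cdf * scale);
        if (L[b] > 255) L[b] = 255;
      }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    // locate column tile pair and weight
    int j1 = 0;
    while (j1 < tiles_c - 1 && tile_cc[j1 + 1] < c) ++j1;
    int j2 = j1;
    double wc = 0.0;
    if (c <= tile_cc[0]) { j1 = j2 = 0; }
    else if (c >= tile_cc[tiles_c - 1]) { j1 = j2 = tiles_c - 1; }
    else {
      j1 = 0;
      while (tile_cc[j1 + 1] < c) ++j1;
      j2 = j1 + 1;
      wc = (c - tile_cc[j1]) / (tile_cc[j2] - tile_cc[j1]);
    }
    for (int r = 0; r < nr; ++r) {
      int i1, i2; double wr = 0.0;
      if (r <= tile_cr[0]) { i1 = i2 = 0; }
      else if (r >= tile_cr[tiles_r - 1]) { i1 = i2 = tiles_r - 1; }
      else {
        i1 = 0;
        while (tile_cr[i1 + 1] < r) ++i1;
        i2 = i1 + 1;
        wr = (r - tile_cr[i1]) / (tile_cr[i2] - tile_cr[i1]);
      }
      int v = img(r, c);
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      double v11 = lut[i1 * tiles_c + j1][v], v12 = lut[i1 * tiles_c + j2][v];
      double v21 = lut[i2 * tiles_c + j1][v], v22 = lut[i2 * tiles_c + j2][v];
      double top = v11 * (1 - wc) + v12 * wc;
      double bot = v21 * (1 - wc) + v22 * wc;
      out(r, c) = (int)std::round(top * (1 - wr) + bot * wr);
    }
  }
  return out;
}
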