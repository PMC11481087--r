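// Low-level voxel kernels for 3D morphometry: separable Gaussian blur,
// Gaussian-weighted median filter, anisotropic squared Euclidean distance
// transform (Felzenszwalb & Huttenlocher lower-envelope algorithm),
// 26/6-connected labelling, marker-controlled watershed (Meyer flooding),
// local-maxima detection and border-connected hole filling.
//
// All arrays are passed flat with an explicit dims vector (n1, n2, n3);
// element (i, j, k), 0-based, lives at i + n1 * (j + n2 * k) — i.e. R's
// column-major layout with axis 1 fastest. Spacing vectors align with dims.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int n1, int n2) {
  return (R_xlen_t)i + (R_xlen_t)n1 * ((R_xlen_t)j + (R_xlen_t)n2 * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, reflecting boundary, truncated at 3 sigma.
// sigma_vox is per-axis in voxel units; sigma <= 0 skips that axis.
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& a, const int n1, const int n2,
                      const int n3, const int axis, const double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += kern[t + r];
  }
  for (double& k : kern) k /= s;

  const int n[3] = {n1, n2, n3};
  const int len = n[axis];
  std::vector<double> line(len), out(len);

  // iterate over all lines along `axis`
  const int na = (axis == 0) ? n2 : n1;
  const int nb = (axis == 2) ? n2 : n3;
  for (int b = 0; b < nb; ++b) {
    for (int a2 = 0; a2 < na; ++a2) {
      for (int t = 0; t < len; ++t) {
        int i, j, k;
        if (axis == 0)      { i = t;  j = a2; k = b; }
        else if (axis == 1) { i = a2; j = t;  k = b; }
        else                { i = a2; j = b;  k = t; }
        line[t] = a[idx3(i, j, k, n1, n2)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        for (int u = -r; u <= r; ++u) {
          int p = t + u;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= len) p = 2 * len - p - 1;
          if (p < 0) p = 0;
          if (p >= len) p = len - 1;
          acc += kern[u + r] * line[p];
        }
        out[t] = acc;
      }
      for (int t = 0; t < len; ++t) {
        int i, j, k;
        if (axis == 0)      { i = t;  j = a2; k = b; }
        else if (axis == 1) { i = a2; j = t;  k = b; }
        else                { i = a2; j = b;  k = t; }
        a[idx3(i, j, k, n1, n2)] = out[t];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector img, IntegerVector dims,
                                  NumericVector sigma_vox) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<double> a(img.begin(), img.end());
  blur_axis(a, n1, n2, n3, 0, sigma_vox[0]);
  blur_axis(a, n1, n2, n3, 1, sigma_vox[1]);
  blur_axis(a, n1, n2, n3, 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  return out;
}

// ---------------------------------------------------------------------------
// Gaussian-weighted median filter. Cubic neighbourhood of Chebyshev radius
// `radius` (voxels), weights exp(-d^2 / (2 sigma^2)) with d the Euclidean
// offset in voxel units; the window is clipped at the border. The weighted
// median is the smallest value v with cumulative weight(values <= v) >= W/2.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_weighted_median3d(NumericVector img, IntegerVector dims,
                                    int radius, double sigma) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(img.size());
  const int r = radius;
  const int wn = (2 * r + 1) * (2 * r + 1) * (2 * r + 1);
  std::vector<double> woff(wn);
  {
    int t = 0;
    for (int dk = -r; dk <= r; ++dk)
      for (int dj = -r; dj <= r; ++dj)
        for (int di = -r; di <= r; ++di, ++t) {
          double d2 = (double)(di * di + dj * dj + dk * dk);
          woff[t] = std::exp(-0.5 * d2 / (sigma * sigma));
        }
  }
  std::vector<std::pair<double, double>> vw;
  vw.reserve(wn);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        vw.clear();
        double W = 0.0;
        int t = 0;
        for (int dk = -r; dk <= r; ++dk)
          for (int dj = -r; dj <= r; ++dj)
            for (int di = -r; di <= r; ++di, ++t) {
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3) continue;
              const double w = woff[t];
              vw.emplace_back(img[idx3(ii, jj, kk, n1, n2)], w);
              W += w;
            }
        std::sort(vw.begin(), vw.end());
        double acc = 0.0, med = vw.back().first;
        for (const auto& p : vw) {
          acc += p.second;
          if (acc >= 0.5 * W) { med = p.first; break; }
        }
        out[idx3(i, j, k, n1, n2)] = med;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform with per-axis spacing.
// Returns, for every voxel, the squared physical distance to the nearest
// voxel where mask == 0 (so foreground voxels get positive distances,
// background gets 0). One-pass-per-axis lower envelope of parabolas.
// ---------------------------------------------------------------------------

static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& v, std::vector<double>& z,
                   const int n, const double s) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    double sp;
    while (true) {
      const double xv = v[k] * s;
      sp = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sp <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sp;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  // finite sentinel larger than any attainable squared distance: keeps the
  // lower-envelope arithmetic NaN-free on all-foreground lines
  double big = 1.0;
  for (int ax = 0; ax < 3; ++ax) {
    const double ext = dims[ax] * spacing[ax];
    big += ext * ext;
  }
  big *= 4.0;
  std::vector<double> a(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t) a[t] = mask[t] ? big : 0.0;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int axis = 0; axis < 3; ++axis) {
    const int n[3] = {n1, n2, n3};
    const int len = n[axis];
    if (len == 1) continue;
    const double s = spacing[axis];
    const int na = (axis == 0) ? n2 : n1;
    const int nb = (axis == 2) ? n2 : n3;
    for (int b = 0; b < nb; ++b)
      for (int a2 = 0; a2 < na; ++a2) {
        for (int t = 0; t < len; ++t) {
          int i, j, k;
          if (axis == 0)      { i = t;  j = a2; k = b; }
          else if (axis == 1) { i = a2; j = t;  k = b; }
          else                { i = a2; j = b;  k = t; }
          f[t] = a[idx3(i, j, k, n1, n2)];
        }
        edt_1d(f, d, v, z, len, s);
        for (int t = 0; t < len; ++t) {
          int i, j, k;
          if (axis == 0)      { i = t;  j = a2; k = b; }
          else if (axis == 1) { i = a2; j = t;  k = b; }
          else                { i = a2; j = b;  k = t; }
          a[idx3(i, j, k, n1, n2)] = d[t];
        }
      }
  }
  NumericVector out(a.begin(), a.end());
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (connectivity 6 or 26), iterative DFS.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> nbr;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nbr.push_back({di, dj, dk});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const R_xlen_t p = idx3(i, j, k, n1, n2);
        if (!mask[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          const R_xlen_t q = stack.back();
          stack.pop_back();
          const int qi = (int)(q % n1);
          const int qj = (int)((q / n1) % n2);
          const int qk = (int)(q / ((R_xlen_t)n1 * n2));
          for (const auto& dv : nbr) {
            const int ii = qi + dv[0], jj = qj + dv[1], kk = qk + dv[2];
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                kk < 0 || kk >= n3) continue;
            const R_xlen_t r = idx3(ii, jj, kk, n1, n2);
            if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by Meyer flooding on a priority image:
// voxels with HIGHER priority are flooded first (pass -elevation to flood
// ascending elevation). Markers are positive integer labels; flooding is
// restricted to mask != 0. Ties broken by insertion order (deterministic).
// ---------------------------------------------------------------------------

struct WsNode {
  double pri;
  unsigned long long ord;
  R_xlen_t idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;   // max-heap on priority
    return a.ord > b.ord;                       // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            IntegerVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector lab(markers.size(), 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  unsigned long long ord = 0;
  const int di6[6] = {-1, 1, 0, 0, 0, 0};
  const int dj6[6] = {0, 0, -1, 1, 0, 0};
  const int dk6[6] = {0, 0, 0, 0, -1, 1};

  for (R_xlen_t p = 0; p < markers.size(); ++p)
    if (markers[p] > 0 && mask[p]) {
      lab[p] = markers[p];
      pq.push({priority[p], ord++, p, markers[p]});
    }

  while (!pq.empty()) {
    const WsNode nd = pq.top();
    pq.pop();
    const int qi = (int)(nd.idx % n1);
    const int qj = (int)((nd.idx / n1) % n2);
    const int qk = (int)(nd.idx / ((R_xlen_t)n1 * n2));
    for (int t = 0; t < 6; ++t) {
      const int ii = qi + di6[t], jj = qj + dj6[t], kk = qk + dk6[t];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
          kk < 0 || kk >= n3) continue;
      const R_xlen_t r = idx3(ii, jj, kk, n1, n2);
      if (!mask[r] || lab[r]) continue;
      lab[r] = nd.lab;
      pq.push({priority[r], ord++, r, nd.lab});
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Local maxima: voxels >= every 26-neighbour inside mask, value > floor.
// Plateaus yield clusters; the caller thins them by minimum separation.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector img, IntegerVector dims,
                               IntegerVector mask, double value_floor) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector out(img.size(), false);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const R_xlen_t p = idx3(i, j, k, n1, n2);
        if (!mask[p] || img[p] <= value_floor) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dj = -1; dj <= 1 && ismax; ++dj)
            for (int di = -1; di <= 1 && ismax; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3) continue;
              if (img[idx3(ii, jj, kk, n1, n2)] > img[p]) ismax = false;
            }
        out[p] = ismax;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Fill holes: background components (6-connected) not reachable from the
// array border become foreground.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<char> outside(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  const int di6[6] = {-1, 1, 0, 0, 0, 0};
  const int dj6[6] = {0, 0, -1, 1, 0, 0};
  const int dk6[6] = {0, 0, 0, 0, -1, 1};
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        if (i != 0 && i != n1 - 1 && j != 0 && j != n2 - 1 &&
            k != 0 && k != n3 - 1) continue;
        const R_xlen_t p = idx3(i, j, k, n1, n2);
        if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  while (!stack.empty()) {
    const R_xlen_t q = stack.back();
    stack.pop_back();
    const int qi = (int)(q % n1);
    const int qj = (int)((q / n1) % n2);
    const int qk = (int)(q / ((R_xlen_t)n1 * n2));
    for (int t = 0; t < 6; ++t) {
      const int ii = qi + di6[t], jj = qj + dj6[t], kk = qk + dk6[t];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
          kk < 0 || kk >= n3) continue;
      const R_xlen_t r = idx3(ii, jj, kk, n1, n2);
      if (!mask[r] && !outside[r]) { outside[r] = 1; stack.push_back(r); }
    }
  }
  IntegerVector out(mask.size());
  for (R_xlen_t p = 0; p < mask.size(); ++p)
    out[p] = mask[p] ? 1 : (outside[p] ? 0 : 1);
  return out;
}
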