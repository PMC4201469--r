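// Low-level numerical kernels: volume sampling, separable Gaussian blur,
// trilinear scatter (adjoint of sampling), joint intensity histograms with
// partial-volume weighting, mutual-information gradients, and majority-vote
// label fusion. All voxel coordinates are 0-based; arrays are in R's
// column-major layout with dimensions (nx, ny, nz).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Sample a 3-D volume at continuous voxel coordinates.
// method: 0 = nearest neighbour, 1 = trilinear.
// edge:   0 = constant fill outside the grid, 1 = clamp to the boundary.
// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector arr, IntegerVector dim, NumericMatrix pts,
                         int method, double fill, int edge) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    double x = pts(r, 0), y = pts(r, 1), z = pts(r, 2);
    if (edge == 1) {
      x = std::min(std::max(x, 0.0), (double)(nx - 1));
      y = std::min(std::max(y, 0.0), (double)(ny - 1));
      z = std::min(std::max(z, 0.0), (double)(nz - 1));
    }
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[r] = fill;
      continue;
    }
    if (method == 0) {
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      out[r] = arr[vidx(i, j, k, nx, ny)];
    } else {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      if (i0 > nx - 2) i0 = nx - 2;
      if (j0 > ny - 2) j0 = ny - 2;
      if (k0 > nz - 2) k0 = nz - 2;
      if (nx == 1) i0 = 0;  // degenerate axes fall back to the single plane
      if (ny == 1) j0 = 0;
      if (nz == 1) k0 = 0;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
          k1 = std::min(k0 + 1, nz - 1);
      double c000 = arr[vidx(i0, j0, k0, nx, ny)], c100 = arr[vidx(i1, j0, k0, nx, ny)];
      double c010 = arr[vidx(i0, j1, k0, nx, ny)], c110 = arr[vidx(i1, j1, k0, nx, ny)];
      double c001 = arr[vidx(i0, j0, k1, nx, ny)], c101 = arr[vidx(i1, j0, k1, nx, ny)];
      double c011 = arr[vidx(i0, j1, k1, nx, ny)], c111 = arr[vidx(i1, j1, k1, nx, ny)];
      double c00 = c000 * (1 - fx) + c100 * fx;
      double c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx;
      double c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[r] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

static inline int reflect_index(int i, int n) {
  // half-sample symmetric reflection: ... c b a | a b c ... | c b a
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(4.0 * sigma);
  std::vector<double> ker(2 * radius + 1);
  double s = 0;
  for (int t = -radius; t <= radius; ++t) {
    ker[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + radius];
  }
  for (double& w : ker) w /= s;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n);
  std::vector<double> res(n);
  // iterate over all lines along `axis`
  int du = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
  int n1 = (axis == 0) ? ny : nx;
  int n2 = (axis == 2) ? ny : nz;
  int d1 = (axis == 0) ? nx : 1;
  int d2 = (axis == 2) ? nx : nx * ny;
  for (int b = 0; b < n2; ++b) {
    for (int a1 = 0; a1 < n1; ++a1) {
      R_xlen_t base = (R_xlen_t)a1 * d1 + (R_xlen_t)b * d2;
      for (int u = 0; u < n; ++u) line[u] = a[base + (R_xlen_t)u * du];
      for (int u = 0; u < n; ++u) {
        double acc = 0;
        for (int t = -radius; t <= radius; ++t)
          acc += ker[t + radius] * line[reflect_index(u + t, n)];
        res[u] = acc;
      }
      for (int u = 0; u < n; ++u) a[base + (R_xlen_t)u * du] = res[u];
    }
  }
}

// Separable Gaussian blur with reflective boundary; sigma per axis in voxels.
// [[Rcpp::export]]
NumericVector cpp_blur3(NumericVector arr, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  blur_axis(a, nx, ny, nz, 0, sigma[0]);
  blur_axis(a, nx, ny, nz, 1, sigma[1]);
  blur_axis(a, nx, ny, nz, 2, sigma[2]);
  NumericVector out(arr.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Adjoint of trilinear sampling: scatter per-point 3-vectors onto a grid with
// trilinear weights. Points are clamped to the grid. Returns (ncell x 3).
// [[Rcpp::export]]
NumericMatrix cpp_scatter3(NumericMatrix pts, NumericMatrix vals, IntegerVector cdim) {
  const int nx = cdim[0], ny = cdim[1], nz = cdim[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(ncell, 3);
  const R_xlen_t n = pts.nrow();
  for (R_xlen_t r = 0; r < n; ++r) {
    double x = std::min(std::max(pts(r, 0), 0.0), (double)(nx - 1));
    double y = std::min(std::max(pts(r, 1), 0.0), (double)(ny - 1));
    double z = std::min(std::max(pts(r, 2), 0.0), (double)(nz - 1));
    int i0 = std::min((int)std::floor(x), std::max(nx - 2, 0));
    int j0 = std::min((int)std::floor(y), std::max(ny - 2, 0));
    int k0 = std::min((int)std::floor(z), std::max(nz - 2, 0));
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double w[8] = {(1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
                   (1 - fx) * fy * (1 - fz),       fx * fy * (1 - fz),
                   (1 - fx) * (1 - fy) * fz,       fx * (1 - fy) * fz,
                   (1 - fx) * fy * fz,             fx * fy * fz};
    R_xlen_t id[8] = {vidx(i0, j0, k0, nx, ny), vidx(i1, j0, k0, nx, ny),
                      vidx(i0, j1, k0, nx, ny), vidx(i1, j1, k0, nx, ny),
                      vidx(i0, j0, k1, nx, ny), vidx(i1, j0, k1, nx, ny),
                      vidx(i0, j1, k1, nx, ny), vidx(i1, j1, k1, nx, ny)};
    for (int c = 0; c < 3; ++c) {
      double v = vals(r, c);
      for (int q = 0; q < 8; ++q) out(id[q], c) += w[q] * v;
    }
  }
  return out;
}

// Joint intensity histogram. pv = 0: hard assignment; pv = 1: linear
// (partial-volume) weighting along both intensity axes. Values are clamped
// to the stated ranges.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int nbins,
                             double amin, double amax, double bmin, double bmax,
                             int pv) {
  NumericMatrix h(nbins, nbins);
  const R_xlen_t n = a.size();
  const double ha = (amax - amin) / nbins, hb = (bmax - bmin) / nbins;
  for (R_xlen_t r = 0; r < n; ++r) {
    double ua = (a[r] - amin) / ha - 0.5;
    double ub = (b[r] - bmin) / hb - 0.5;
    if (pv == 0) {
      int i = (int)std::floor(ua + 0.5), j = (int)std::floor(ub + 0.5);
      i = std::min(std::max(i, 0), nbins - 1);
      j = std::min(std::max(j, 0), nbins - 1);
      h(i, j) += 1.0;
    } else {
      ua = std::min(std::max(ua, 0.0), (double)(nbins - 1));
      ub = std::min(std::max(ub, 0.0), (double)(nbins - 1));
      int i0 = std::min((int)std::floor(ua), nbins - 2);
      int j0 = std::min((int)std::floor(ub), nbins - 2);
      double fa = ua - i0, fb = ub - j0;
      h(i0, j0)         += (1 - fa) * (1 - fb);
      h(i0 + 1, j0)     += fa * (1 - fb);
      h(i0, j0 + 1)     += (1 - fa) * fb;
      h(i0 + 1, j0 + 1) += fa * fb;
    }
  }
  return h;
}

// Mutual information (nats) of a fixed reference `a` (hard-binned) against a
// moving image `b` (linearly binned), plus the per-sample derivative of MI
// with respect to b's intensity. Used by the MI-driven non-linear stage.
// [[Rcpp::export]]
List cpp_mi_grad(NumericVector a, NumericVector b, int nbins,
                 double amin, double amax, double bmin, double bmax) {
  const R_xlen_t n = a.size();
  const double ha = (amax - amin) / nbins, hb = (bmax - bmin) / nbins;
  std::vector<int> ai(n);
  std::vector<int> bj(n);
  std::vector<double> bf(n);
  std::vector<char> clamped(n);
  std::vector<double> h((size_t)nbins * nbins, 0.0);
  for (R_xlen_t r = 0; r < n; ++r) {
    double ua = (a[r] - amin) / ha - 0.5;
    int i = (int)std::floor(ua + 0.5);
    i = std::min(std::max(i, 0), nbins - 1);
    ai[r] = i;
    double ub = (b[r] - bmin) / hb - 0.5;
    char cl = (ub <= 0.0 || ub >= nbins - 1) ? 1 : 0;
    ub = std::min(std::max(ub, 0.0), (double)(nbins - 1));
    int j0 = std::min((int)std::floor(ub), nbins - 2);
    double f = ub - j0;
    bj[r] = j0; bf[r] = f; clamped[r] = cl;
    h[(size_t)i + (size_t)nbins * j0] += 1 - f;
    h[(size_t)i + (size_t)nbins * (j0 + 1)] += f;
  }
  std::vector<double> pi(nbins, 0.0), qj(nbins, 0.0);
  double tot = (double)n;
  for (int j = 0; j < nbins; ++j)
    for (int i = 0; i < nbins; ++i) {
      pi[i] += h[(size_t)i + (size_t)nbins * j];
      qj[j] += h[(size_t)i + (size_t)nbins * j];
    }
  const double eps = 1e-12;
  double mi = 0;
  for (int j = 0; j < nbins; ++j)
    for (int i = 0; i < nbins; ++i) {
      double p = h[(size_t)i + (size_t)nbins * j] / tot;
      if (p > eps)
        mi += p * std::log(p * tot * tot / (pi[i] * qj[j]));
    }
  NumericVector grad(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    if (clamped[r]) { grad[r] = 0; continue; }
    int i = ai[r], j0 = bj[r];
    double p0 = h[(size_t)i + (size_t)nbins * j0];
    double p1 = h[(size_t)i + (size_t)nbins * (j0 + 1)];
    double l0 = std::log((p0 + eps) / (qj[j0] + eps));
    double l1 = std::log((p1 + eps) / (qj[j0 + 1] + eps));
    grad[r] = (l1 - l0) / (tot * hb);
  }
  return List::create(_["mi"] = mi, _["grad"] = grad);
}

// Majority-vote label fusion across K voters per voxel. Ties are broken by
// preferring a nonzero label over background, then the smallest nonzero id.
// [[Rcpp::export]]
IntegerVector cpp_label_fuse(IntegerMatrix labs) {
  const R_xlen_t n = labs.nrow();
  const int K = labs.ncol();
  IntegerVector out(n);
  std::vector<int> vals(K);
  std::vector<int> cnts(K);
  for (R_xlen_t r = 0; r < n; ++r) {
    int m = 0;
    for (int k = 0; k < K; ++k) {
      int v = labs(r, k);
      int f = -1;
      for (int q = 0; q < m; ++q)
        if (vals[q] == v) { f = q; break; }
      if (f >= 0) cnts[f]++;
      else { vals[m] = v; cnts[m] = 1; ++m; }
    }
    int maxc = 0;
    for (int q = 0; q < m; ++q) maxc = std::max(maxc, cnts[q]);
    int best = -1;
    for (int q = 0; q < m; ++q) {
      if (cnts[q] != maxc) continue;
      int v = vals[q];
      if (best == -1) best = v;
      else if (best == 0 && v != 0) best = v;
      else if (v != 0 && v < best) best = v;
    }
    out[r] = best;
  }
  return out;
}
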