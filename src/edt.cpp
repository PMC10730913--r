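#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
// f: input squared distances (INF where no site); d: output; n: length.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * (q - v[k]));
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * (q - v[k]));
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared EDT of a binary mask over a (h x w) window, distances between
// pixel centers in pixel units.
static void edt_window(const std::vector<char>& mask, int h, int w,
                       std::vector<double>& out) {
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  // column pass
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) f[i] = mask[(size_t)j * h + i] ? 0.0 : INF;
    dt1d(f, d, h);
    for (int i = 0; i < h; ++i) out[(size_t)j * h + i] = d[i];
  }
  // row pass
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) f[j] = out[(size_t)j * h + i];
    dt1d(f, d, w);
    for (int j = 0; j < w; ++j) out[(size_t)j * h + i] = d[j];
  }
}

// Distance-capped generalized Voronoi expansion of a nucleus label image.
// For each label (ascending), the exact Euclidean distance to the label's
// pixel mask is computed on a bounding box padded by the cap; each pixel takes
// the label of the strictly nearest mask, so equidistant ties resolve to the
// lowest label id. Pixels farther than max_px from every mask keep label 0.
// Returns squared distances (pixel units) and the winning labels.
// [[Rcpp::export]]
List edt_label_capped(IntegerMatrix labels, double max_px) {
  const int H = labels.nrow(), W = labels.ncol();
  NumericMatrix dist2(H, W);
  IntegerMatrix out(H, W);
  std::fill(dist2.begin(), dist2.end(), INF);

  int maxlab = 0;
  for (int idx = 0; idx < H * W; ++idx)
    if (labels[idx] > maxlab) maxlab = labels[idx];
  if (maxlab == 0) return List::create(_["dist2"] = dist2, _["label"] = out);

  // bounding boxes per label
  std::vector<int> rmin(maxlab + 1, H), rmax(maxlab + 1, -1),
                   cmin(maxlab + 1, W), cmax(maxlab + 1, -1);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int L = labels(i, j);
      if (L > 0) {
        if (i < rmin[L]) rmin[L] = i;
        if (i > rmax[L]) rmax[L] = i;
        if (j < cmin[L]) cmin[L] = j;
        if (j > cmax[L]) cmax[L] = j;
      }
    }

  const int pad = (int)std::ceil(max_px) + 1;
  const double cap2 = max_px * max_px;
  std::vector<char> mask;
  std::vector<double> wd;
  for (int L = 1; L <= maxlab; ++L) {
    if (rmax[L] < 0) continue;
    int r0 = std::max(0, rmin[L] - pad), r1 = std::min(H - 1, rmax[L] + pad);
    int c0 = std::max(0, cmin[L] - pad), c1 = std::min(W - 1, cmax[L] + pad);
    int h = r1 - r0 + 1, w = c1 - c0 + 1;
    mask.assign((size_t)h * w, 0);
    for (int j = c0; j <= c1; ++j)
      for (int i = r0; i <= r1; ++i)
        if (labels(i, j) == L) mask[(size_t)(j - c0) * h + (i - r0)] = 1;
    wd.assign((size_t)h * w, INF);
    edt_window(mask, h, w, wd);
    for (int j = c0; j <= c1; ++j)
      for (int i = r0; i <= r1; ++i) {
        double d2 = wd[(size_t)(j - c0) * h + (i - r0)];
        if (d2 <= cap2 && d2 < dist2(i, j)) {
          dist2(i, j) = d2;
          out(i, j) = L;
        }
      }
  }
  return List::create(_["dist2"] = dist2, _["label"] = out);
}
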