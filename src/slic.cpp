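// Grid-seeded local k-means superpixels (SLIC-style) on a grayscale image.
// Distance: (dI / m)^2 + (dr^2 + dc^2) / s^2, with s the seed spacing and m
// an intensity tolerance; each pixel only competes among seeds within a 2s
// window, so the cost is O(iters * H * W).
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cpp_slic(NumericMatrix img, int K, double m, int iters) {
  const int H = img.nrow(), W = img.ncol();
  if (K < 1) stop("K must be >= 1");
  const double s = std::sqrt((double)H * W / K);
  std::vector<double> cr, cc, ci;
  for (double r = s / 2; r < H; r += s)
    for (double c = s / 2; c < W; c += s) {
      cr.push_back(r);
      cc.push_back(c);
      ci.push_back(img((int)r, (int)c));
    }
  const int nc = (int)cr.size();
  std::vector<int> lab((size_t)H * W, 0);
  std::vector<double> best((size_t)H * W);

  for (int it = 0; it < iters; ++it) {
    std::fill(best.begin(), best.end(), 1e30);
    for (int k = 0; k < nc; ++k) {
      const int r0 = std::max(0, (int)(cr[k] - 2 * s)),
                r1 = std::min(H, (int)(cr[k] + 2 * s) + 1),
                c0 = std::max(0, (int)(cc[k] - 2 * s)),
                c1 = std::min(W, (int)(cc[k] + 2 * s) + 1);
      for (int c = c0; c < c1; ++c) {
        for (int r = r0; r < r1; ++r) {
          const double dI = (img(r, c) - ci[k]) / m;
          const double dr = r - cr[k], dc = c - cc[k];
          const double d = dI * dI + (dr * dr + dc * dc) / (s * s);
          const size_t p = (size_t)c * H + r;
          if (d < best[p]) { best[p] = d; lab[p] = k; }
        }
      }
    }
    std::vector<double> sr(nc, 0), sc(nc, 0), si(nc, 0), n(nc, 0);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const int k = lab[(size_t)c * H + r];
        sr[k] += r; sc[k] += c; si[k] += img(r, c); n[k] += 1;
      }
    for (int k = 0; k < nc; ++k)
      if (n[k] > 0) { cr[k] = sr[k] / n[k]; cc[k] = sc[k] / n[k]; ci[k] = si[k] / n[k]; }
  }

  // compact label ids to 1..K' over non-empty clusters
  std::vector<int> remap(nc, -1);
  int next = 0;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const int k = lab[(size_t)c * H + r];
      if (remap[k] < 0) remap[k] = ++next;
      out(r, c) = remap[k];
    }
  return out;
}
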