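// Centre-anchored bilinear rotation with zero fill, used by the training
// augmentation pipeline (shape-preserving, unlike canvas-growing rotations).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".rotate_bilinear")]]
NumericMatrix rotate_bilinear(const NumericMatrix &img, double angle_deg) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int j = 0; j < W; ++j) {
    const double dx = j - cx;
    for (int i = 0; i < H; ++i) {
      const double dy = i - cy;
      // inverse mapping: sample the source at the back-rotated position
      const double sy = cy + ct * dy - st * dx;
      const double sx = cx + st * dy + ct * dx;
      const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      if (y0 < -1 || y0 > H - 1 || x0 < -1 || x0 > W - 1) continue;
      const double fy = sy - y0, fx = sx - x0;
      double v = 0.0;
      for (int oy = 0; oy <= 1; ++oy) {
        for (int ox = 0; ox <= 1; ++ox) {
          const int yy = y0 + oy, xx = x0 + ox;
          if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
          const double wgt = (oy ? fy : 1 - fy) * (ox ? fx : 1 - fx);
          v += wgt * img(yy, xx);
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}
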