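#include <Rcpp.h>
using namespace Rcpp;

// Max-composite Gaussian cross-sections along a densely sampled centerline.
// canvas holds the running maximum of amplitude * exp(-r^2 / (2 sigma^2))
// contributions; row/col are 0-based pixel coordinates of the samples
// (pixel centres at integer coordinates), sigma in pixels.
// [[Rcpp::export]]
NumericMatrix paint_gaussian_max(NumericMatrix canvas, NumericVector row,
                                 NumericVector col, NumericVector sigma,
                                 double amplitude) {
  int H = canvas.nrow(), W = canvas.ncol(), n = row.size();
  for (int k = 0; k < n; ++k) {
    double rr = row[k], cc = col[k], sg = sigma[k];
    if (sg <= 0) continue;
    double inv2s2 = 1.0 / (2.0 * sg * sg);
    int rad = (int)std::ceil(3.5 * sg) + 1;
    int r0 = std::max(0, (int)std::floor(rr) - rad);
    int r1 = std::min(H - 1, (int)std::ceil(rr) + rad);
    int c0 = std::max(0, (int)std::floor(cc) - rad);
    int c1 = std::min(W - 1, (int)std::ceil(cc) + rad);
    for (int c = c0; c <= c1; ++c) {
      double dc = c - cc;
      for (int r = r0; r <= r1; ++r) {
        double dr = r - rr;
        double v = amplitude * std::exp(-(dr * dr + dc * dc) * inv2s2);
        if (v > canvas(r, c)) canvas(r, c) = v;
      }
    }
  }
  return canvas;
}
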