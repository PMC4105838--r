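#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling by breadth-first flood fill.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int cur = 0;
  std::vector<std::pair<int, int> > queue;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++cur;
      queue.clear();
      queue.push_back(std::make_pair(r, c));
      lab(r, c) = cur;
      while (!queue.empty()) {
        std::pair<int, int> q = queue.back();
        queue.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = q.first + dr, cc = q.second + dc;
            if (rr < 0 || cc < 0 || rr >= H || cc >= W) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = cur;
              queue.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
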