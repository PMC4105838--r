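#include <Rcpp.h>
using namespace Rcpp;

// Topology-preserving thinning of a binary mask to an 8-connected,
// one-pixel-wide skeleton: Zhang-Suen parallel thinning followed by a
// sequential pass that deletes redundant simple pixels (crossing number 1,
// 2..6 neighbours) so that staircase corners do not survive and inflate
// chain-code lengths.

static inline int at(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// neighbours clockwise from north: P2..P9
static void nbrs(const IntegerMatrix &m, int r, int c, int p[8]) {
  p[0] = at(m, r - 1, c);     // N
  p[1] = at(m, r - 1, c + 1); // NE
  p[2] = at(m, r, c + 1);     // E
  p[3] = at(m, r + 1, c + 1); // SE
  p[4] = at(m, r + 1, c);     // S
  p[5] = at(m, r + 1, c - 1); // SW
  p[6] = at(m, r, c - 1);     // W
  p[7] = at(m, r - 1, c - 1); // NW
}

static inline int transitions(const int p[8]) {
  int a = 0;
  for (int i = 0; i < 8; ++i) a += (p[i] == 0 && p[(i + 1) % 8] == 1);
  return a;
}

static inline int count(const int p[8]) {
  int b = 0;
  for (int i = 0; i < 8; ++i) b += p[i];
  return b;
}

// Yokoi connectivity number for 8-connected foreground: 1 means the pixel is
// simple (deletable without changing topology). p is ordered N, NE, E, SE,
// S, SW, W, NW; the formula runs over the four orthogonal directions.
static inline int yokoi8(const int p[8]) {
  // reorder to b[0]=E, b[1]=NE, b[2]=N, ... counter-clockwise
  int b[8] = {p[2], p[1], p[0], p[7], p[6], p[5], p[4], p[3]};
  int cn = 0;
  for (int k = 0; k < 8; k += 2) {
    int bk = 1 - b[k], b1 = 1 - b[(k + 1) % 8], b2 = 1 - b[(k + 2) % 8];
    cn += bk - bk * b1 * b2;
  }
  return cn;
}

// [[Rcpp::export]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) m(r, c) = mask(r, c) ? 1 : 0;

  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!m(r, c)) continue;
          int p[8];
          nbrs(m, r, c, p);
          int B = count(p);
          if (B < 2 || B > 6) continue;
          if (transitions(p) != 1) continue;
          // p[0]=N, p[2]=E, p[4]=S, p[6]=W
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = 0;
    }
  }

  // sequential cleanup: delete remaining simple pixels (staircase corners)
  // while preserving endpoints, leaving a minimal 8-connected skeleton
  changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (!m(r, c)) continue;
        int p[8];
        nbrs(m, r, c, p);
        int B = count(p);
        if (B >= 2 && yokoi8(p) == 1) {
          m(r, c) = 0;
          changed = true;
        }
      }
    }
  }

  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) out(r, c) = m(r, c) == 1;
  return out;
}
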