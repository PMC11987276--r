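// Binary-morphology primitives used by the vessel morphometry and phantom
// modules: Zhang-Suen thinning, 8-neighbour counts on skeletons, and a
// distance-based anti-aliased rasteriser for parametric centerline curves.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Zhang-Suen thinning of a binary matrix (0/1). Preserves connectivity and
// yields an (approximately) 1-px-wide 8-connected skeleton.
// [[Rcpp::export]]
IntegerMatrix zhang_suen_thin_cpp(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  std::vector<int> img((H + 2) * (W + 2), 0); // 1-px zero border
  auto at = [&](int r, int c) -> int& { return img[(c + 1) * (H + 2) + (r + 1)]; };
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) at(r, c) = mask(r, c) ? 1 : 0;

  std::vector<std::pair<int, int>> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!at(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p[8] = {at(r - 1, c),     at(r - 1, c + 1), at(r, c + 1),
                      at(r + 1, c + 1), at(r + 1, c),     at(r + 1, c - 1),
                      at(r, c - 1),     at(r - 1, c - 1)};
          int B = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.emplace_back(r, c);
        }
      }
      for (auto& rc : del) at(rc.first, rc.second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  // serial cleanup: Zhang-Suen's parallel deletion leaves 2-px staircase
  // residue whose pixels read as fake junctions. A pixel is redundant when
  // its foreground neighbours form a single 8-connected component among
  // themselves (then its removal cannot disconnect anything) and it is not
  // an endpoint. Deleting serially until stable yields a minimal skeleton.
  const int dr8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc8[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  bool removed = true;
  while (removed) {
    removed = false;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (!at(r, c)) continue;
        int nbr[8], nn = 0;
        for (int k = 0; k < 8; ++k)
          if (at(r + dr8[k], c + dc8[k])) nbr[nn++] = k;
        if (nn < 2) continue;
        // union-find over the <= 8 neighbours with true 8-adjacency
        int comp[8];
        for (int i = 0; i < nn; ++i) comp[i] = i;
        for (int i = 0; i < nn; ++i) {
          for (int j = i + 1; j < nn; ++j) {
            int ddr = dr8[nbr[i]] - dr8[nbr[j]];
            int ddc = dc8[nbr[i]] - dc8[nbr[j]];
            if (ddr >= -1 && ddr <= 1 && ddc >= -1 && ddc <= 1) {
              int ci = comp[i], cj = comp[j];
              if (ci != cj)
                for (int t = 0; t < nn; ++t)
                  if (comp[t] == cj) comp[t] = ci;
            }
          }
        }
        int ncomp = 0;
        for (int i = 0; i < nn; ++i) if (comp[i] == i) ++ncomp;
        if (ncomp == 1) { at(r, c) = 0; removed = true; }
      }
    }
  }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) out(r, c) = at(r, c);
  return out;
}

// 8-connectivity neighbour count for every foreground pixel (0 elsewhere).
// [[Rcpp::export]]
IntegerMatrix neighbor_count_cpp(const IntegerMatrix& skel) {
  int H = skel.nrow(), W = skel.ncol();
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!skel(r, c)) continue;
      int n = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W && skel(rr, cc)) ++n;
        }
      out(r, c) = n;
    }
  }
  return out;
}

// Anti-aliased rendering of polyline tubes. Points: n x 2 (row, col),
// half-width per point. Returns H x W coverage field in [0,1]:
// clamp(0.5 + (halfwidth - distance), 0, 1), maximised over all tubes.
// `curve_id` marks breaks (distance never measured across different curves).
// [[Rcpp::export]]
NumericMatrix render_tubes_cpp(int H, int W, const NumericVector& row,
                               const NumericVector& col, const NumericVector& halfwidth,
                               const IntegerVector& curve_id) {
  NumericMatrix field(H, W); // zero-initialised
  int n = row.size();
  for (int i = 0; i + 1 < n; ++i) {
    if (curve_id[i] != curve_id[i + 1]) continue;
    double r0 = row[i], c0 = col[i], r1 = row[i + 1], c1 = col[i + 1];
    double w0 = halfwidth[i], w1 = halfwidth[i + 1];
    double wmax = std::max(w0, w1) + 1.0;
    int rlo = std::max(0, (int)std::floor(std::min(r0, r1) - wmax));
    int rhi = std::min(H - 1, (int)std::ceil(std::max(r0, r1) + wmax));
    int clo = std::max(0, (int)std::floor(std::min(c0, c1) - wmax));
    int chi = std::min(W - 1, (int)std::ceil(std::max(c0, c1) + wmax));
    double dr = r1 - r0, dc = c1 - c0;
    double len2 = dr * dr + dc * dc;
    for (int c = clo; c <= chi; ++c) {
      for (int r = rlo; r <= rhi; ++r) {
        double t = 0.0;
        if (len2 > 0)
          t = std::max(0.0, std::min(1.0, ((r - r0) * dr + (c - c0) * dc) / len2));
        double pr = r0 + t * dr, pc = c0 + t * dc;
        double d = std::sqrt((r - pr) * (r - pr) + (c - pc) * (c - pc));
        double hw = w0 + t * (w1 - w0);
        double cov = 0.5 + (hw - d);
        if (cov > 1.0) cov = 1.0;
        if (cov > field(r, c)) field(r, c) = cov;
      }
    }
  }
  return field;
}
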