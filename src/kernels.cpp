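#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 8-neighborhood offsets, clockwise starting north
static const int DR8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC8[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Connected-component labeling with row-major discovery order, so that
// label ids are deterministic across runs. connectivity must be 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < 8; ++k) {
          if (connectivity == 4 && (k % 2 == 1)) continue;
          int rr = p.first + DR8[k], cc = p.second + DC8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && labels(rr, cc) == 0) {
            labels(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return labels;
}

// Region growing from a single seed over the 8-connected foreground
// component. Records every background pixel 8-adjacent to a claimed pixel
// as boundary, in encounter order. Coordinates returned 1-based (row, col).
// [[Rcpp::export]]
List region_grow_cpp(LogicalMatrix mask, int seed_r, int seed_c) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (seed_r < 1 || seed_r > nr || seed_c < 1 || seed_c > nc)
    stop("seed outside image bounds");
  int sr = seed_r - 1, sc = seed_c - 1;
  if (!mask(sr, sc)) stop("seed is not a foreground pixel");
  LogicalMatrix claimed(nr, nc), on_boundary(nr, nc);
  std::vector<int> ir, ic, br, bc;
  std::queue<std::pair<int, int> > q;
  claimed(sr, sc) = true;
  q.push(std::make_pair(sr, sc));
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    ir.push_back(p.first + 1);
    ic.push_back(p.second + 1);
    for (int k = 0; k < 8; ++k) {
      int rr = p.first + DR8[k], cc = p.second + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc)) {
        if (!claimed(rr, cc)) {
          claimed(rr, cc) = true;
          q.push(std::make_pair(rr, cc));
        }
      } else if (!on_boundary(rr, cc)) {
        on_boundary(rr, cc) = true;
        br.push_back(rr + 1);
        bc.push_back(cc + 1);
      }
    }
  }
  int ni = ir.size(), nb = br.size();
  IntegerMatrix interior(ni, 2), boundary(nb, 2);
  for (int i = 0; i < ni; ++i) { interior(i, 0) = ir[i]; interior(i, 1) = ic[i]; }
  for (int i = 0; i < nb; ++i) { boundary(i, 0) = br[i]; boundary(i, 1) = bc[i]; }
  return List::create(_["interior"] = interior, _["boundary"] = boundary);
}

// Moore-neighbor contour tracing of the region `label` in a label image.
// Returns the ordered closed contour (1-based coordinates, start point not
// repeated) and its length with axial steps 1 and diagonal steps sqrt(2).
// [[Rcpp::export]]
List trace_contour_cpp(IntegerMatrix labels, int label) {
  int nr = labels.nrow(), nc = labels.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (labels(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) stop("label not present in image");

  std::vector<int> pr, pc;
  pr.push_back(sr + 1);
  pc.push_back(sc + 1);
  double len = 0.0;

  // backtrack direction: west of the start pixel (outside the region by
  // row-major-first construction)
  int cr = sr, cc = sc, back = 6; // index of west in DR8/DC8
  int first_move = -1;
  long guard = 8L * (long)nr * (long)nc + 16;
  while (guard-- > 0) {
    int found = -1;
    for (int i = 1; i <= 8; ++i) {
      int k = (back + i) % 8;
      int rr = cr + DR8[k], ccol = cc + DC8[k];
      if (rr < 0 || rr >= nr || ccol < 0 || ccol >= nc) continue;
      if (labels(rr, ccol) == label) { found = k; break; }
    }
    if (found < 0) break; // isolated single pixel
    if (first_move < 0) first_move = found;
    else if (cr == sr && cc == sc && found == first_move) break; // Jacob's criterion
    len += (found % 2 == 0) ? 1.0 : std::sqrt(2.0);
    // new backtrack = the last examined background neighbor (the cell just
    // before `found` in the clockwise scan), re-indexed from the new pixel
    int prev = (found + 7) % 8;
    int rel_r = DR8[prev] - DR8[found], rel_c = DC8[prev] - DC8[found];
    for (int k = 0; k < 8; ++k)
      if (DR8[k] == rel_r && DC8[k] == rel_c) { back = k; break; }
    cr += DR8[found];
    cc += DC8[found];
    if (cr == sr && cc == sc) {
      // candidate stop; loop re-enters to test Jacob's criterion
      continue;
    }
    pr.push_back(cr + 1);
    pc.push_back(cc + 1);
  }
  int n = pr.size();
  IntegerMatrix path(n, 2);
  for (int i = 0; i < n; ++i) { path(i, 0) = pr[i]; path(i, 1) = pc[i]; }
  return List::create(_["path"] = path, _["length"] = len);
}

static inline int nbrs_of(const LogicalMatrix& m, int r, int c, int* p) {
  int nr = m.nrow(), nc = m.ncol(), b = 0;
  for (int k = 0; k < 8; ++k) {
    int rr = r + DR8[k], cc = c + DC8[k];
    p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc && m(rr, cc)) ? 1 : 0;
    b += p[k];
  }
  return b;
}

// Two-subiteration morphological thinning (Zhang-Suen) to a 1-px skeleton,
// preserving connectivity of the foreground.
// [[Rcpp::export]]
LogicalMatrix thin_zs_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  int p[8]; // p[0]=N(p2), p[1]=NE(p3), ..., p[7]=NW(p9)
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      std::vector<std::pair<int, int> > kill;
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int B = nbrs_of(img, r, c, p);
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k) A += (p[k] == 0 && p[(k + 1) % 8] == 1);
          if (A != 1) continue;
          // p2=p[0] N, p4=p[2] E, p6=p[4] S, p8=p[6] W
          if (sub == 0) {
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
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = false;
    }
  }
  return img;
}

// Prune skeleton spurs by iterative tip erosion: min_len passes, each
// removing every pixel whose crossing number is <= 1 (free line ends,
// isolated pixels, and stubs attached diagonally to a trunk). Free-ended
// branches shorter than min_len disappear entirely; longer branches are
// shortened by min_len but keep their branch point. Closed loops and
// interior line pixels (crossing number 2) are untouched.
// [[Rcpp::export]]
LogicalMatrix prune_spurs_cpp(LogicalMatrix skel, int min_len) {
  int nr = skel.nrow(), nc = skel.ncol();
  LogicalMatrix img = clone(skel);
  int p[8];
  for (int pass = 0; pass < min_len; ++pass) {
    std::vector<std::pair<int, int> > kill;
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        if (!img(r, c)) continue;
        nbrs_of(img, r, c, p);
        int A = 0;
        for (int k = 0; k < 8; ++k) A += (p[k] == 0 && p[(k + 1) % 8] == 1);
        if (A <= 1) kill.push_back(std::make_pair(r, c));
      }
    if (kill.empty()) break;
    for (size_t i = 0; i < kill.size(); ++i)
      img(kill[i].first, kill[i].second) = false;
  }
  return img;
}
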