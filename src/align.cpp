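#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment over a 128x128 char-indexed score
// matrix. mode "local" = Smith-Waterman, mode "global" = Needleman-Wunsch.
// Gap of length L costs gap_open + L * gap_ext (gap_open, gap_ext >= 0).
//
// Returns 0-based half-open coordinates of the aligned region in both
// sequences plus a run-length CIGAR-like op list:
//   M consumes one base of each, D consumes a only, I consumes b only.

static inline int idx(size_t i, size_t j, size_t m) { return (int)(i * m + j); }

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, IntegerMatrix smat,
               int gap_open, int gap_ext, std::string mode) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  if ((n + 1) * (m + 1) > 80000000ULL)
    stop("alignment problem too large (%d x %d)", (int)n, (int)m);
  const bool local = (mode == "local");
  const int NEG = -1000000000;
  const size_t W = m + 1;

  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback: tb*: which matrix the best path came from (0=M,1=X,2=Y,3=stop)
  std::vector<unsigned char> tbM((n + 1) * W, 3), tbX((n + 1) * W, 0),
      tbY((n + 1) * W, 0);

  M[idx(0, 0, W)] = 0;
  for (size_t j = 1; j <= m; ++j) {
    if (local) {
      M[idx(0, j, W)] = 0;
    } else {
      Y[idx(0, j, W)] = -(gap_open + (int)j * gap_ext);
      tbY[idx(0, j, W)] = (j == 1) ? 0 : 2;
    }
  }
  for (size_t i = 1; i <= n; ++i) {
    if (local) {
      M[idx(i, 0, W)] = 0;
    } else {
      X[idx(i, 0, W)] = -(gap_open + (int)i * gap_ext);
      tbX[idx(i, 0, W)] = (i == 1) ? 0 : 1;
    }
  }

  int best = 0;
  size_t bi = 0, bj = 0;
  for (size_t i = 1; i <= n; ++i) {
    const int ca = (unsigned char)a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      const int cb = (unsigned char)b[j - 1];
      const int s = smat(ca, cb);
      const size_t k = idx(i, j, W), kd = idx(i - 1, j - 1, W),
                   ku = idx(i - 1, j, W), kl = idx(i, j - 1, W);
      // X: gap in b (consume a)
      int xo = (M[ku] == NEG) ? NEG : M[ku] - gap_open - gap_ext;
      int xe = (X[ku] == NEG) ? NEG : X[ku] - gap_ext;
      if (xo >= xe) { X[k] = xo; tbX[k] = 0; } else { X[k] = xe; tbX[k] = 1; }
      // Y: gap in a (consume b)
      int yo = (M[kl] == NEG) ? NEG : M[kl] - gap_open - gap_ext;
      int ye = (Y[kl] == NEG) ? NEG : Y[kl] - gap_ext;
      if (yo >= ye) { Y[k] = yo; tbY[k] = 0; } else { Y[k] = ye; tbY[k] = 2; }
      // M: diagonal
      int dm = M[kd], dx = X[kd], dy = Y[kd];
      int d = dm; unsigned char t = 0;
      if (dx > d) { d = dx; t = 1; }
      if (dy > d) { d = dy; t = 2; }
      int v = (d == NEG) ? NEG : d + s;
      if (local && v < 0) { v = 0; t = 3; }
      M[k] = v; tbM[k] = t;
      if (local && v > best) { best = v; bi = i; bj = j; }
    }
  }

  int which_end = 0; // 0=M,1=X,2=Y
  if (!local) {
    bi = n; bj = m;
    const size_t k = idx(n, m, W);
    best = M[k]; which_end = 0;
    if (X[k] > best) { best = X[k]; which_end = 1; }
    if (Y[k] > best) { best = Y[k]; which_end = 2; }
  }

  // traceback
  std::vector<char> ops;
  size_t i = bi, j = bj;
  int cur = which_end;
  while (true) {
    if (local && cur == 0 && M[idx(i, j, W)] == 0 && tbM[idx(i, j, W)] == 3)
      break;
    if (!local && i == 0 && j == 0) break;
    const size_t k = idx(i, j, W);
    if (cur == 0) {
      unsigned char t = tbM[k];
      if (local && t == 3) break;
      ops.push_back('M');
      cur = t; --i; --j;
      if (local && cur == 0 && (i == 0 || j == 0)) break;
      if (!local && i == 0 && j == 0) break;
    } else if (cur == 1) {
      ops.push_back('D');
      cur = tbX[k] == 0 ? 0 : 1;
      --i;
    } else {
      ops.push_back('I');
      cur = tbY[k] == 0 ? 0 : 2;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::vector<char> rops; std::vector<int> rlens;
  for (char o : ops) {
    if (!rops.empty() && rops.back() == o) rlens.back()++;
    else { rops.push_back(o); rlens.push_back(1); }
  }
  CharacterVector opv(rops.size());
  IntegerVector lenv(rlens.size());
  for (size_t q = 0; q < rops.size(); ++q) {
    opv[q] = std::string(1, rops[q]);
    lenv[q] = rlens[q];
  }

  return List::create(
      _["score"] = best,
      _["a_start"] = (int)i, _["a_end"] = (int)bi,
      _["b_start"] = (int)j, _["b_end"] = (int)bj,
      _["op"] = opv, _["len"] = lenv);
}

// Best local (maximum-sum) segment of an integer score vector; used by the
// per-diagonal seeded extension of the translated matcher. Returns up to
// `max_segments` disjoint segments with sum >= min_score, best first.
// [[Rcpp::export]]
List cpp_best_segments(IntegerVector v, int min_score, int max_segments) {
  const int n = v.size();
  std::vector<bool> used(n, false);
  std::vector<int> starts, ends, scores;
  for (int seg = 0; seg < max_segments; ++seg) {
    int best = min_score - 1, bs = -1, be = -1;
    int cur = 0, cs = 0;
    for (int i = 0; i < n; ++i) {
      if (used[i]) { cur = 0; cs = i + 1; continue; }
      cur += v[i];
      if (cur <= 0) { cur = 0; cs = i + 1; continue; }
      if (cur > best) { best = cur; bs = cs; be = i; }
    }
    if (bs < 0) break;
    starts.push_back(bs); ends.push_back(be); scores.push_back(best);
    for (int i = bs; i <= be; ++i) used[i] = true;
  }
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                      _["score"] = wrap(scores));
}
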