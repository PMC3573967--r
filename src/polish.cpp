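#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Deterministic greedy local search over an alignment map: per pass the best
// single move is applied until no move improves the score. Moves:
//   - reassign row i to a free column (or unalign it);
//   - exchange the targets of rows i and j (covers partner transfers when
//     one of them is unaligned).
// BA/BA2 hold 1-based edge-weight bin indices, SAL/SNA the s_aligned /
// s_not_aligned lookups per (i, i2), row_na the row sums of SNA. map0 is
// 0-based, -1 = unaligned. Returns the improved map (0-based).
// [[Rcpp::export]]
IntegerVector polish_alignment_cpp(IntegerMatrix BA, IntegerMatrix BA2,
                                   NumericMatrix s_edge,
                                   NumericMatrix SAL, NumericMatrix SNA,
                                   NumericVector row_na,
                                   IntegerVector map0, int max_passes) {
  const int N = BA.nrow(), N2 = BA2.nrow();
  std::vector<int> map(map0.begin(), map0.end());
  std::vector<char> used(N2, 0);
  for (int i = 0; i < N; ++i)
    if (map[i] >= 0) used[map[i]] = 1;

  // vertex term of pairing i with t (exact score change vs unaligned)
  auto V = [&](int i, int t) -> double {
    if (t < 0) return 0.0;
    return SAL(i, t) + row_na[i] - SNA(i, t);
  };
  // edge terms of row i against all currently aligned rows except skip
  auto edge_sum = [&](int i, int t, int skip) -> double {
    if (t < 0) return 0.0;
    double s = 0.0;
    for (int j = 0; j < N; ++j) {
      if (j == i || j == skip || map[j] < 0) continue;
      s += s_edge(BA(i, j) - 1, BA2(t, map[j]) - 1);
    }
    return s;
  };

  for (int pass = 0; pass < max_passes; ++pass) {
    double best_delta = 1e-12;
    int best_kind = -1, bi = -1, bj = -1, bt = -1;

    // reassignment moves
    for (int i = 0; i < N; ++i) {
      const int told = map[i];
      const double base = V(i, told) + edge_sum(i, told, -1);
      for (int t = -1; t < N2; ++t) {
        if (t == told) continue;
        if (t >= 0 && used[t]) continue;
        double delta = V(i, t) + edge_sum(i, t, -1) - base;
        if (delta > best_delta) {
          best_delta = delta; best_kind = 0; bi = i; bt = t;
        }
      }
    }

    // exchange moves
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        const int ti = map[i], tj = map[j];
        if (ti < 0 && tj < 0) continue;
        double delta = V(i, tj) + V(j, ti) - V(i, ti) - V(j, tj);
        delta += edge_sum(i, tj, j) - edge_sum(i, ti, j);
        delta += edge_sum(j, ti, i) - edge_sum(j, tj, i);
        if (ti >= 0 && tj >= 0)
          delta += s_edge(BA(i, j) - 1, BA2(tj, ti) - 1) -
                   s_edge(BA(i, j) - 1, BA2(ti, tj) - 1);
        if (delta > best_delta) {
          best_delta = delta; best_kind = 1; bi = i; bj = j;
        }
      }
    }

    if (best_kind == -1) break;
    if (best_kind == 0) {
      if (map[bi] >= 0) used[map[bi]] = 0;
      map[bi] = bt;
      if (bt >= 0) used[bt] = 1;
    } else {
      std::swap(map[bi], map[bj]);
    }
  }

  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = map[i];
  return out;
}
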