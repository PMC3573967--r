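#include <Rcpp.h>
using namespace Rcpp;

// Edge part of the linearised assignment matrix:
//   M[i, i2] = sum over currently aligned j (j != i) of
//              s_edge(bin A[i, j], bin A2[i2, cur(j)])
// For directed networks the reversed edge pair (j, i) / (cur(j), i2) is added
// as well. BA/BA2 hold 1-based bin indices of the adjacency matrices;
// cur_from/cur_to are 1-based vertex indices of the current alignment.
// [[Rcpp::export]]
NumericMatrix assignment_edge_term_cpp(IntegerMatrix BA, IntegerMatrix BA2,
                                       NumericMatrix s_edge,
                                       IntegerVector cur_from,
                                       IntegerVector cur_to,
                                       bool directed) {
  const int N = BA.nrow(), N2 = BA2.nrow(), k = cur_from.size();
  NumericMatrix M(N, N2);
  for (int t = 0; t < k; ++t) {
    const int jf = cur_from[t] - 1;
    const int jt = cur_to[t] - 1;
    IntegerMatrix::Column bcol = BA.column(jf);    // bin A[., jf]
    IntegerMatrix::Column bcol2 = BA2.column(jt);  // bin A2[., jt]
    for (int i2 = 0; i2 < N2; ++i2) {
      NumericMatrix::Column se = s_edge.column(bcol2[i2] - 1);
      NumericMatrix::Column mcol = M.column(i2);
      for (int i = 0; i < N; ++i) {
        if (i == jf) continue;
        mcol[i] += se[bcol[i] - 1];
      }
    }
    if (directed) {
      // reversed direction: s_edge(bin A[jf, i], bin A2[jt, i2])
      for (int i2 = 0; i2 < N2; ++i2) {
        const int b2 = BA2(jt, i2);
        NumericMatrix::Column se = s_edge.column(b2 - 1);
        NumericMatrix::Column mcol = M.column(i2);
        for (int i = 0; i < N; ++i) {
          if (i == jf) continue;
          mcol[i] += se[BA(jf, i) - 1];
        }
      }
    }
  }
  return M;
}
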