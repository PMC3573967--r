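#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dense linear assignment by successive shortest augmenting paths with dual
// potentials (the Jonker-Volgenant family). Minimisation; requires
// nrow <= ncol; every row is assigned. Returns 1-based column indices.
// [[Rcpp::export]]
IntegerVector lap_min_cpp(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr > nc) stop("lap_min_cpp requires nrow <= ncol");
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (!R_finite(cost(i, j))) stop("cost matrix has non-finite entries");

  std::vector<double> u(nr, 0.0), v(nc, 0.0), shortest(nc);
  std::vector<int> row4col(nc, -1), col4row(nr, -1), pred(nc, -1);
  std::vector<char> SR(nr), SC(nc);

  for (int curRow = 0; curRow < nr; ++curRow) {
    double minVal = 0.0;
    int i = curRow, sink = -1;
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(shortest.begin(), shortest.end(), R_PosInf);

    while (sink == -1) {
      SR[i] = 1;
      double lowest = R_PosInf;
      int jlow = -1;
      for (int j = 0; j < nc; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { shortest[j] = r; pred[j] = i; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1 && jlow != -1 &&
             row4col[jlow] != -1)) {
          lowest = shortest[j];
          jlow = j;
        }
      }
      minVal = lowest;
      if (jlow == -1 || !R_finite(minVal))
        stop("linear assignment is infeasible");
      SC[jlow] = 1;
      if (row4col[jlow] == -1) sink = jlow; else i = row4col[jlow];
    }

    u[curRow] += minVal;
    for (int ii = 0; ii < nr; ++ii)
      if (SR[ii] && ii != curRow)
        u[ii] += minVal - shortest[col4row[ii]];
    for (int j = 0; j < nc; ++j)
      if (SC[j])
        v[j] -= minVal - shortest[j];

    // augment along the alternating path back to curRow
    int j = sink;
    while (true) {
      int ii = pred[j];
      row4col[j] = ii;
      std::swap(col4row[ii], j);
      if (ii == curRow) break;
    }
  }

  IntegerVector out(nr);
  for (int ii = 0; ii < nr; ++ii) out[ii] = col4row[ii] + 1;
  return out;
}
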