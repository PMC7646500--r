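#include <Rcpp.h>
using namespace Rcpp;

// Semi-global dynamic programming over mask-encoded degenerate sequences.
//
// q and r hold IUPAC base-set bitmasks (A=1, C=2, G=4, T=8; e.g. R = 5).
// A ref value of 0 marks an all-gap alignment column: skipping it costs
// nothing and aligning a base onto it scores the mismatch value.
// scoreTab is a 16x16 per-column score table indexed by mask value.
// With freeEndGaps, leading/trailing gaps on either sequence are free and
// the optimum is taken over the last row and column.
//
// Traceback tie-break: diagonal > deletion (gap in query) > insertion.

// [[Rcpp::export(name = ".semiglobalDP")]]
List semiglobalDP(IntegerVector q, IntegerVector r, IntegerMatrix scoreTab,
                  int indel, bool freeEndGaps) {
  const int n = q.size(), m = r.size();
  std::vector< std::vector<int> > H(n + 1, std::vector<int>(m + 1, 0));
  std::vector< std::vector<unsigned char> > P(
      n + 1, std::vector<unsigned char>(m + 1, 3));
  for (int i = 1; i <= n; ++i) {
    H[i][0] = freeEndGaps ? 0 : i * indel;
    if (!freeEndGaps) P[i][0] = 2;
  }
  for (int j = 1; j <= m; ++j) {
    int dc = (r[j - 1] == 0) ? 0 : indel;
    H[0][j] = freeEndGaps ? 0 : H[0][j - 1] + dc;
    if (!freeEndGaps) P[0][j] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int diag = H[i - 1][j - 1] + scoreTab(q[i - 1], r[j - 1]);
      const int del  = H[i][j - 1] + ((r[j - 1] == 0) ? 0 : indel);
      const int ins  = H[i - 1][j] + indel;
      int best = diag; unsigned char p = 0;
      if (del > best) { best = del; p = 1; }
      if (ins > best) { best = ins; p = 2; }
      H[i][j] = best; P[i][j] = p;
    }
  }
  int ie = n, je = m, bestScore = H[n][m];
  if (freeEndGaps) {
    for (int i = n; i >= 0; --i)
      if (H[i][m] > bestScore) { bestScore = H[i][m]; ie = i; je = m; }
    for (int j = m; j >= 0; --j)
      if (H[n][j] > bestScore) { bestScore = H[n][j]; ie = n; je = j; }
  }
  std::vector<int> ops, colQ, colR, colS;
  int i = ie, j = je;
  while (i > 0 || j > 0) {
    const unsigned char p = P[i][j];
    if (p == 3) break;  // free-end boundary
    if (p == 0) {
      ops.push_back(0);
      colQ.push_back(i - 1); colR.push_back(j - 1);
      colS.push_back(scoreTab(q[i - 1], r[j - 1]));
      --i; --j;
    } else if (p == 1) {
      ops.push_back(1); --j;
    } else {
      ops.push_back(2); --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(colQ.begin(), colQ.end());
  std::reverse(colR.begin(), colR.end());
  std::reverse(colS.begin(), colS.end());
  return List::create(
      _["score"] = bestScore,
      _["qstart"] = i, _["qend"] = ie,
      _["rstart"] = j, _["rend"] = je,
      _["ops"] = wrap(ops),
      _["colQuery"] = wrap(colQ),
      _["colRef"] = wrap(colR),
      _["colScore"] = wrap(colS));
}
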