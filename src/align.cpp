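#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps and a
// bisulfite-aware substitution rule: reference 'C' aligned to query 'T'
// scores as a match (unmethylated cytosines read as T after conversion).
// Tie-breaking is deterministic ("high-road"): diagonal, then up (gap in
// query, consuming reference), then left.
//
// Returns: ref_to_query (1-based query index per reference base, 0 when
// the reference base is deleted in the query), score, n_match (matching
// columns, bisulfite C/T counted as match), n_cols (aligned columns).
// [[Rcpp::export(name = ".align_bisulfite")]]
List align_bisulfite(std::string ref, std::string query,
                     double match = 2.0, double mismatch = -2.0,
                     double gap_open = -5.0, double gap_extend = -1.0) {
  const int n = ref.size(), m = query.size();
  if (n == 0 || m == 0)
    stop("sequences must be non-empty");
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: which state each cell came from (0=M,1=X,2=Y)
  std::vector<signed char> tbM((n + 1) * W, -1), tbX((n + 1) * W, -1),
      tbY((n + 1) * W, -1);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_extend;
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + (j - 1) * gap_extend;
    tbY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    char rc = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      char qc = query[j - 1];
      bool is_match = (rc == qc) || (rc == 'C' && qc == 'T');
      double s = is_match ? match : mismatch;
      int c = i * W + j, d = (i - 1) * W + (j - 1);
      // M: prefer M >= X >= Y on ties
      double best = M[d]; signed char from = 0;
      if (X[d] > best) { best = X[d]; from = 1; }
      if (Y[d] > best) { best = Y[d]; from = 2; }
      M[c] = best + s; tbM[c] = from;
      // X (up; gap in query): open from M/Y, extend from X
      int u = (i - 1) * W + j;
      double xo = M[u] + gap_open, xe = X[u] + gap_extend,
             xy = Y[u] + gap_open;
      X[c] = xo; tbX[c] = 0;
      if (xe > X[c]) { X[c] = xe; tbX[c] = 1; }
      if (xy > X[c]) { X[c] = xy; tbX[c] = 2; }
      // Y (left; gap in reference)
      int l = i * W + (j - 1);
      double yo = M[l] + gap_open, ye = Y[l] + gap_extend,
             yx = X[l] + gap_open;
      Y[c] = yo; tbY[c] = 0;
      if (yx > Y[c]) { Y[c] = yx; tbY[c] = 1; }
      if (ye > Y[c]) { Y[c] = ye; tbY[c] = 2; }
    }
  }
  int e = n * W + m;
  int state = 0;
  double score = M[e];
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }
  IntegerVector ref_to_query(n, 0);
  int i = n, j = m, n_match = 0, n_cols = 0;
  while (i > 0 || j > 0) {
    int c = i * W + j;
    ++n_cols;
    if (state == 0) {
      char rc = ref[i - 1], qc = query[j - 1];
      if (rc == qc || (rc == 'C' && qc == 'T')) ++n_match;
      ref_to_query[i - 1] = j;
      state = tbM[c];
      --i; --j;
    } else if (state == 1) {        // gap in query: ref base unaligned
      state = tbX[c];
      --i;
    } else {                        // gap in reference
      state = tbY[c];
      --j;
    }
  }
  return List::create(_["ref_to_query"] = ref_to_query,
                      _["score"] = score, _["n_match"] = n_match,
                      _["n_cols"] = n_cols);
}
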