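#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment score between two integer-coded symbol
// sequences (1-based codes indexing rows/cols of `sub`).  `gap` is the
// additive score of aligning a symbol against an inserted gap (<= 0 in any
// sane scheme; the package default is 0).
// [[Rcpp::export]]
double nw_score_cpp(IntegerVector a, IntegerVector b,
                    NumericMatrix sub, double gap) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; j++) prev[j] = j * gap;
  for (int i = 1; i <= n; i++) {
    cur[0] = i * gap;
    int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; j++) {
      double diag = prev[j - 1] + sub(ai, b[j - 1] - 1);
      double up   = prev[j] + gap;
      double left = cur[j - 1] + gap;
      cur[j] = std::max(diag, std::max(up, left));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Dynamic time warping between two numeric sequences with squared local
// cost, full window, symmetric step pattern.  Returns the accumulated cost
// and the optimal warping path (1-based index pairs) needed for barycenter
// averaging.
// [[Rcpp::export]]
List dtw_path_cpp(NumericVector x, NumericVector y) {
  int n = x.size(), m = y.size();
  NumericMatrix D(n + 1, m + 1);
  const double inf = std::numeric_limits<double>::infinity();
  for (int j = 0; j <= m; j++) D(0, j) = inf;
  for (int i = 0; i <= n; i++) D(i, 0) = inf;
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      double d = x[i - 1] - y[j - 1];
      double best = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = d * d + best;
    }
  }
  // backtrack
  std::vector<int> pi, pj;
  int i = n, j = m;
  pi.push_back(i); pj.push_back(j);
  while (i > 1 || j > 1) {
    double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
    if (diag <= up && diag <= left) { i--; j--; }
    else if (up <= left)            { i--; }
    else                            { j--; }
    pi.push_back(i); pj.push_back(j);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = D(n, m),
                      _["index1"] = IntegerVector(pi.begin(), pi.end()),
                      _["index2"] = IntegerVector(pj.begin(), pj.end()));
}

// Accumulated-cost-only DTW (no path), used for medoid selection and the
// barycenter objective.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y) {
  int n = x.size(), m = y.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; i++) {
    cur[0] = inf;
    for (int j = 1; j <= m; j++) {
      double d = x[i - 1] - y[j - 1];
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), inf);
  }
  return prev[m];
}
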