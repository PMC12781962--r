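#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping by full dynamic programming over the n x m cost
// matrix with steps {down, right, diagonal}. Series here are at most 50
// points, so no warping window is applied. Backtracking prefers the
// diagonal predecessor on ties (affects the reported path only, never the
// distance).

// distance-only variant used by the classifier's inner loops: two rolling
// rows, no path bookkeeping
// [[Rcpp::export(name = ".dtw_dist_cpp")]]
double dtw_dist_cpp(NumericVector a, NumericVector b, bool squared) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = a[i] - b[j];
      c = squared ? c * c : std::fabs(c);
      if (i == 0 && j == 0) {
        cur[j] = c;
      } else if (i == 0) {
        cur[j] = c + cur[j - 1];
      } else if (j == 0) {
        cur[j] = c + prev[j];
      } else {
        double best = prev[j - 1];
        if (prev[j] < best) best = prev[j];
        if (cur[j - 1] < best) best = cur[j - 1];
        cur[j] = c + best;
      }
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export(name = ".dtw_cpp")]]
List dtw_cpp(NumericVector a, NumericVector b, bool squared, bool normalize) {
  const int n = a.size(), m = b.size();
  NumericMatrix D(n, m);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = a[i] - b[j];
      c = squared ? c * c : std::fabs(c);
      if (i == 0 && j == 0) {
        D(i, j) = c;
      } else if (i == 0) {
        D(i, j) = c + D(i, j - 1);
      } else if (j == 0) {
        D(i, j) = c + D(i - 1, j);
      } else {
        double best = D(i - 1, j - 1);
        if (D(i - 1, j) < best) best = D(i - 1, j);
        if (D(i, j - 1) < best) best = D(i, j - 1);
        D(i, j) = c + best;
      }
    }
  }

  // backtrack from (n-1, m-1); diagonal preferred on ties
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1);
  pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) {
      --j;
    } else if (j == 0) {
      --i;
    } else {
      double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
      if (diag <= up && diag <= left) {
        --i;
        --j;
      } else if (up <= left) {
        --i;
      } else {
        --j;
      }
    }
    pi.push_back(i + 1);
    pj.push_back(j + 1);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }

  double dist = D(n - 1, m - 1);
  if (normalize) dist /= L;
  return List::create(_["distance"] = dist, _["path"] = path);
}
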