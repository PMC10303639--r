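#include <Rcpp.h>
using namespace Rcpp;

// Local distance matrix between two multiview sequences.
// A, B: L x M and L x N matrices (rows = views); d[m,n] = sum_l (A(l,m)-B(l,n))^2
// (squared Euclidean across views, no square root).
// [[Rcpp::export]]
NumericMatrix cpp_local_distance(NumericMatrix A, NumericMatrix B) {
  const int L = A.nrow(), M = A.ncol(), N = B.ncol();
  if (B.nrow() != L) stop("view count mismatch between the two sequences");
  NumericMatrix d(M, N);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      for (int l = 0; l < L; ++l) {
        const double diff = A(l, m) - B(l, n);
        s += diff * diff;
      }
      d(m, n) = s;
    }
  }
  return d;
}

// Accumulated DTW path-distance table and optimal path.
// Recurrence: D[m,n] = d[m,n] + min(D[m-1,n], D[m-1,n-1], D[m,n-1]),
// D[0,0] = d[0,0], out-of-range predecessors treated as +inf.
// Backtracking from the terminal cell prefers the diagonal predecessor,
// then (m-1,n), then (m,n-1) on ties. Path indices returned 1-based.
// [[Rcpp::export]]
List cpp_dtw_table(NumericMatrix d) {
  const int M = d.nrow(), N = d.ncol();
  if (M == 0 || N == 0) stop("empty local distance matrix");
  NumericMatrix D(M, N);
  const double inf = R_PosInf;
  for (int m = 0; m < M; ++m) {
    for (int n = 0; n < N; ++n) {
      double best;
      if (m == 0 && n == 0) best = 0.0;
      else {
        best = inf;
        if (m > 0 && n > 0 && D(m - 1, n - 1) < best) best = D(m - 1, n - 1);
        if (m > 0 && D(m - 1, n) < best) best = D(m - 1, n);
        if (n > 0 && D(m, n - 1) < best) best = D(m, n - 1);
      }
      D(m, n) = d(m, n) + best;
    }
  }
  // backtrack
  std::vector<int> pm, pn;
  int m = M - 1, n = N - 1;
  pm.push_back(m + 1); pn.push_back(n + 1);
  while (m > 0 || n > 0) {
    double diag = (m > 0 && n > 0) ? D(m - 1, n - 1) : inf;
    double up   = (m > 0) ? D(m - 1, n) : inf;
    double left = (n > 0) ? D(m, n - 1) : inf;
    if (diag <= up && diag <= left)      { --m; --n; }
    else if (up <= left)                 { --m; }
    else                                 { --n; }
    pm.push_back(m + 1); pn.push_back(n + 1);
  }
  const int K = (int) pm.size();
  IntegerMatrix path(K, 2);
  for (int k = 0; k < K; ++k) { // reverse to run (1,1) -> (M,N)
    path(k, 0) = pm[K - 1 - k];
    path(k, 1) = pn[K - 1 - k];
  }
  return List::create(_["D"] = D, _["path"] = path);
}
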