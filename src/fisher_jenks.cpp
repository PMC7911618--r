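#include <Rcpp.h>
using namespace Rcpp;

// Fisher's optimal contiguous partition (the exact algorithm behind
// Jenks natural breaks) of sorted unique values u with multiplicities w
// into L classes, minimizing the total within-class weighted sum of
// squared deviations. Running on unique values guarantees equal values
// are never split across classes; an optimum of this form always exists
// because merging a tied run into the nearer-mean class cannot increase
// the cost. O(L * n^2) dynamic program.
//
// Returns the 0-based index into u of the first value of classes 2..L.
// [[Rcpp::export]]
IntegerVector fisher_jenks_starts(NumericVector u, NumericVector w, int L) {
  const int n = u.size();
  if (L < 1 || n < L) stop("need at least L distinct values");
  std::vector<double> cw(n + 1, 0.0), cwx(n + 1, 0.0), cwx2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cw[i + 1] = cw[i] + w[i];
    cwx[i + 1] = cwx[i] + w[i] * u[i];
    cwx2[i + 1] = cwx2[i] + w[i] * u[i] * u[i];
  }
  auto cost = [&](int i, int j) {  // values i..j inclusive
    const double W = cw[j + 1] - cw[i];
    const double S = cwx[j + 1] - cwx[i];
    const double S2 = cwx2[j + 1] - cwx2[i];
    double c = S2 - S * S / W;
    return c > 0.0 ? c : 0.0;
  };
  std::vector<std::vector<double> > D(L, std::vector<double>(n, 0.0));
  std::vector<std::vector<int> > B(L, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) D[0][i] = cost(0, i);
  for (int k = 1; k < L; ++k) {
    for (int i = k; i < n; ++i) {
      double best = R_PosInf;
      int arg = k;
      for (int j = k; j <= i; ++j) {  // class k+1 starts at value j
        const double c = D[k - 1][j - 1] + cost(j, i);
        if (c < best) { best = c; arg = j; }
      }
      D[k][i] = best;
      B[k][i] = arg;
    }
  }
  IntegerVector starts(L - 1);
  int i = n - 1;
  for (int k = L - 1; k >= 1; --k) {
    const int j = B[k][i];
    starts[k - 1] = j;
    i = j - 1;
  }
  return starts;
}
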