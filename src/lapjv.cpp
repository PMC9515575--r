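#include <Rcpp.h>
#include <vector>
#include <limits>

// Exact solution of the square linear assignment problem by shortest
// augmenting paths with dual potentials (Jonker-Volgenant style, O(n^3)).
// Used for empirical 1-Wasserstein distance between equal-size samples
// under uniform weights: W = (1/n) * minimal total matched cost.

// [[Rcpp::export]]
Rcpp::List lapjv_cpp(Rcpp::NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) Rcpp::stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  // potentials and matching; arrays are 1-based on rows with sentinel col 0
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0);    // p[j] = row matched to column j
  std::vector<int> way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  Rcpp::IntegerVector assign(n);
  double total = 0.0;
  for (int j = 1; j <= n; ++j) {
    if (p[j] > 0) {
      assign[p[j] - 1] = j;            // row p[j] -> column j (1-based)
      total += cost(p[j] - 1, j - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("assignment") = assign,
                            Rcpp::Named("total_cost") = total);
}
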