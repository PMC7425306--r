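#include <Rcpp.h>
using namespace Rcpp;

// Weighted global efficiency: mean over ordered node pairs of the inverse
// shortest-path length, with edge lengths 1/weight and disconnected pairs
// contributing 0. All-pairs distances by Floyd-Warshall, which at the
// network sizes used here (<= a few hundred nodes) beats repeated
// heap-based searches.
// [[Rcpp::export]]
double global_efficiency_cpp(NumericMatrix w) {
  int n = w.nrow();
  if (n < 2) return 0.0;
  std::vector<double> d((size_t)n * n);
  const double inf = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      d[(size_t)i * n + j] = (i == j) ? 0.0 : (w(i, j) > 0 ? 1.0 / w(i, j)
                                                           : inf);
  for (int k = 0; k < n; ++k) {
    const double *dk = &d[(size_t)k * n];
    for (int i = 0; i < n; ++i) {
      double dik = d[(size_t)i * n + k];
      if (dik == inf) continue;
      double *di = &d[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        double alt = dik + dk[j];
        if (alt < di[j]) di[j] = alt;
      }
    }
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && d[(size_t)i * n + j] < inf)
        acc += 1.0 / d[(size_t)i * n + j];
  return acc / ((double)n * (n - 1));
}
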