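#include <Rcpp.h>
using namespace Rcpp;

NumericVector assign_weights_cpp(IntegerMatrix el, NumericVector weights,
                                 NumericVector s_target, int n,
                                 int swap_iters);
double global_efficiency_cpp(NumericMatrix w);

// Onnela weighted clustering coefficient (weights scaled by the network
// maximum, geometric-mean triangle intensity, binary degree in the
// denominator; degree < 2 contributes 0).
// [[Rcpp::export]]
double clustering_onnela_cpp(NumericMatrix w) {
  int n = w.nrow();
  double mx = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (w(i, j) > mx) mx = w(i, j);
  if (mx <= 0) return 0.0;
  std::vector<double> cw((size_t)n * n);
  std::vector<int> deg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = w(i, j);
      cw[(size_t)i * n + j] = v > 0 ? std::cbrt(v / mx) : 0.0;
      if (v > 0 && i != j) ++deg[i];
    }
  // cyc_i = (CW^3)_ii via B = CW^2 then sum_j B_ij * CW_ij; the diagonal of
  // CW is zero, so i = j = k exclusions are automatic
  std::vector<double> B((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *ci = &cw[(size_t)i * n];
    for (int k = 0; k < n; ++k) {
      double cik = ci[k];
      if (cik == 0.0) continue;
      const double *ck = &cw[(size_t)k * n];
      double *bi = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j) bi[j] += cik * ck[j];
    }
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    if (deg[i] < 2) continue;
    double cyc = 0.0;
    const double *ci = &cw[(size_t)i * n];
    const double *bi = &B[(size_t)i * n];
    for (int j = 0; j < n; ++j) cyc += bi[j] * ci[j];
    acc += cyc / ((double)deg[i] * (deg[i] - 1));
  }
  return acc / n;
}

// Maslov-Sneppen degree-preserving double-edge swaps on an edge list
// (1-based node indices). `niter` swap attempts; swaps creating self-loops
// or duplicate edges are rejected. Modifies a copy; uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix ms_rewire_cpp(IntegerMatrix el, int n, int niter) {
  int E = el.nrow();
  IntegerMatrix out = clone(el);
  int *c0 = INTEGER(out);          // column 0
  int *c1 = c0 + E;                // column 1
  std::vector<char> adj((size_t)n * n, 0);
  for (int e = 0; e < E; ++e) {
    int a = c0[e] - 1, b = c1[e] - 1;
    adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = 1;
  }
  for (int it = 0; it < niter; ++it) {
    int e = (int)(unif_rand() * E), f = (int)(unif_rand() * E);
    if (e >= E) e = E - 1;
    if (f >= E) f = E - 1;
    if (e == f) continue;
    int a = c0[e] - 1, b = c1[e] - 1;
    int c = c0[f] - 1, d = c1[f] - 1;
    // randomly choose one of the two swap orientations
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;           // would duplicate the pair
    if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue;
    adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = 0;
    adj[(size_t)c * n + d] = adj[(size_t)d * n + c] = 0;
    adj[(size_t)a * n + d] = adj[(size_t)d * n + a] = 1;
    adj[(size_t)c * n + b] = adj[(size_t)b * n + c] = 1;
    c0[e] = a + 1;
    c1[e] = d + 1;
    c0[f] = c + 1;
    c1[f] = b + 1;
  }
  return out;
}

// single-precision efficiency for the null ensembles: the null-mean
// normalizers are Monte-Carlo estimates, so float accuracy is ample and the
// narrower type roughly doubles the Floyd-Warshall throughput
static double efficiency_float(const std::vector<float> &w, int n) {
  const float inf = std::numeric_limits<float>::infinity();
  std::vector<float> d((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      float wij = w[(size_t)i * n + j];
      d[(size_t)i * n + j] = (i == j) ? 0.0f : (wij > 0 ? 1.0f / wij : inf);
    }
  for (int k = 0; k < n; ++k) {
    const float *dk = &d[(size_t)k * n];
    for (int i = 0; i < n; ++i) {
      float dik = d[(size_t)i * n + k];
      if (dik == inf) continue;
      float *di = &d[(size_t)i * n];
      for (int j = 0; j < n; ++j) {
        float alt = dik + dk[j];
        if (alt < di[j]) di[j] = alt;
      }
    }
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && d[(size_t)i * n + j] < inf)
        acc += 1.0 / (double)d[(size_t)i * n + j];
  return acc / ((double)n * (n - 1));
}

static double clustering_float(const std::vector<float> &w, int n) {
  float mx = 0.0f;
  for (size_t t = 0; t < w.size(); ++t)
    if (w[t] > mx) mx = w[t];
  if (mx <= 0) return 0.0;
  std::vector<float> cw((size_t)n * n);
  std::vector<int> deg(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      float v = w[(size_t)i * n + j];
      cw[(size_t)i * n + j] = v > 0 ? std::cbrt(v / mx) : 0.0f;
      if (v > 0 && i != j) ++deg[i];
    }
  std::vector<float> B((size_t)n * n, 0.0f);
  for (int i = 0; i < n; ++i) {
    const float *ci = &cw[(size_t)i * n];
    for (int k = 0; k < n; ++k) {
      float cik = ci[k];
      if (cik == 0.0f) continue;
      const float *ck = &cw[(size_t)k * n];
      float *bi = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j) bi[j] += cik * ck[j];
    }
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    if (deg[i] < 2) continue;
    double cyc = 0.0;
    const float *ci = &cw[(size_t)i * n];
    const float *bi = &B[(size_t)i * n];
    for (int j = 0; j < n; ++j) cyc += (double)bi[j] * ci[j];
    acc += cyc / ((double)deg[i] * (deg[i] - 1));
  }
  return acc / n;
}

// Fused null-ensemble metric computation: for each of n_nulls surrogates,
// rewire the topology, re-assign the weight multiset (rank matching + swap
// descent) and compute global efficiency and Onnela clustering, without
// materializing the matrices on the R side. Returns an n_nulls x 2 matrix
// (efficiency, clustering).
// [[Rcpp::export]]
NumericMatrix null_metrics_cpp(IntegerMatrix el, NumericVector weights,
                               NumericVector s_target, int n, int niter,
                               int swap_iters, int n_nulls) {
  NumericMatrix res(n_nulls, 2);
  std::vector<float> w((size_t)n * n);
  for (int r = 0; r < n_nulls; ++r) {
    IntegerMatrix el2 = ms_rewire_cpp(el, n, niter);
    NumericVector wn = assign_weights_cpp(el2, weights, s_target, n,
                                          swap_iters);
    std::fill(w.begin(), w.end(), 0.0f);
    for (int e = 0; e < el2.nrow(); ++e) {
      int a = el2(e, 0) - 1, b = el2(e, 1) - 1;
      w[(size_t)a * n + b] = w[(size_t)b * n + a] = (float)wn[e];
    }
    res(r, 0) = efficiency_float(w, n);
    res(r, 1) = clustering_float(w, n);
  }
  return res;
}
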