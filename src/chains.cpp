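#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Random-transposition chains for the spectral permutation tests.  All
// randomness flows through R's RNG (callers seed with set.seed), so traces
// are reproducible and can be replayed against from-scratch oracles.

static inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Fisher-Yates shuffle of v using R's RNG
static void shuffle_vec(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// Two-sample chain.  X: (m+n) x (kappa+1) matrix of heat-weighted
// (embedded) coefficient vectors, rows 0..m-1 group A, m..m+n-1 group B at
// the observed arrangement.  At each step a cross-group pair of slots is
// drawn uniformly, the group means are updated by the transposition
// increments, and the squared L2 norm of the mean difference is recorded.
// Every `rerandomize_every` steps (0 = never) all labels are re-randomized
// and the means recomputed from scratch.
// [[Rcpp::export]]
List two_sample_chain_cpp(NumericMatrix X, int m, int n, int steps,
                          int rerandomize_every, bool record_labels) {
  const int N = m + n, K = X.ncol();
  std::vector<int> slotA(m), slotB(n);
  for (int i = 0; i < m; ++i) slotA[i] = i;
  for (int j = 0; j < n; ++j) slotB[j] = m + j;

  std::vector<double> meanA(K, 0.0), meanB(K, 0.0);
  auto recompute = [&]() {
    std::fill(meanA.begin(), meanA.end(), 0.0);
    std::fill(meanB.begin(), meanB.end(), 0.0);
    for (int i = 0; i < m; ++i)
      for (int k = 0; k < K; ++k) meanA[k] += X(slotA[i], k);
    for (int j = 0; j < n; ++j)
      for (int k = 0; k < K; ++k) meanB[k] += X(slotB[j], k);
    for (int k = 0; k < K; ++k) { meanA[k] /= m; meanB[k] /= n; }
  };
  recompute();

  NumericVector trace(steps);
  IntegerMatrix labels;
  if (record_labels) labels = IntegerMatrix(steps, N);

  std::vector<int> pool(N);
  for (int t = 1; t <= steps; ++t) {
    if (rerandomize_every > 0 && t % rerandomize_every == 0) {
      int p = 0;
      for (int i = 0; i < m; ++i) pool[p++] = slotA[i];
      for (int j = 0; j < n; ++j) pool[p++] = slotB[j];
      shuffle_vec(pool);
      for (int i = 0; i < m; ++i) slotA[i] = pool[i];
      for (int j = 0; j < n; ++j) slotB[j] = pool[m + j];
      recompute();
    } else {
      int i = runif_int(m), j = runif_int(n);
      int a = slotA[i], b = slotB[j];
      for (int k = 0; k < K; ++k) {
        double xa = X(a, k), xb = X(b, k);
        meanA[k] += (xb - xa) / m;
        meanB[k] += (xa - xb) / n;
      }
      slotA[i] = b; slotB[j] = a;
    }
    double stat = 0.0;
    for (int k = 0; k < K; ++k) {
      double d = meanA[k] - meanB[k];
      stat += d * d;
    }
    trace[t - 1] = stat;
    if (record_labels) {
      for (int i = 0; i < m; ++i) labels(t - 1, slotA[i]) = 1;
    }
  }
  List out = List::create(_["trace"] = trace);
  if (record_labels) out["labels"] = labels;
  return out;
}

// T-ANOVA chain.  D: N x N matrix of pairwise squared L2 distances,
// labels0: initial group labels 1..K.  Group labels for a transposition are
// drawn proportionally to group sizes (first group ~ n_i/N, second among the
// rest ~ n_i/(N - n_{i1})), subjects uniformly within groups.  TSSW/TSSB are
// updated incrementally via per-subject group row sums; every
// `rerandomize_every` steps labels are fully re-randomized (sizes conserved)
// and the sums recomputed directly.
// [[Rcpp::export]]
List tanova_chain_cpp(NumericMatrix D, IntegerVector labels0, int steps,
                      int rerandomize_every, bool record_labels) {
  const int N = D.nrow();
  int K = 0;
  for (int i = 0; i < N; ++i) K = std::max(K, labels0[i]);
  std::vector<int> lab(N);
  for (int i = 0; i < N; ++i) lab[i] = labels0[i] - 1;

  std::vector<std::vector<int>> members(K);
  auto rebuild_members = [&]() {
    for (int g = 0; g < K; ++g) members[g].clear();
    for (int i = 0; i < N; ++i) members[lab[i]].push_back(i);
  };
  rebuild_members();
  std::vector<int> sizes(K);
  for (int g = 0; g < K; ++g) sizes[g] = (int)members[g].size();

  // G(s, g) = sum of D(s, j) over j currently in group g
  std::vector<double> G((size_t)N * K, 0.0);
  double TSSW = 0.0, TSSB = 0.0;
  auto recompute = [&]() {
    std::fill(G.begin(), G.end(), 0.0);
    for (int s = 0; s < N; ++s)
      for (int j = 0; j < N; ++j) G[(size_t)s * K + lab[j]] += D(s, j);
    TSSW = 0.0; TSSB = 0.0;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (lab[i] == lab[j]) TSSW += D(i, j); else TSSB += D(i, j);
      }
  };
  recompute();

  NumericVector phi_trace(steps), tssb_trace(steps), tssw_trace(steps);
  IntegerMatrix labmat;
  if (record_labels) labmat = IntegerMatrix(steps, N);
  std::vector<int> pool(N);

  for (int t = 1; t <= steps; ++t) {
    if (rerandomize_every > 0 && t % rerandomize_every == 0) {
      for (int i = 0; i < N; ++i) pool[i] = i;
      shuffle_vec(pool);
      int p = 0;
      for (int g = 0; g < K; ++g)
        for (int c = 0; c < sizes[g]; ++c) lab[pool[p++]] = g;
      rebuild_members();
      recompute();
    } else {
      // group i1 with prob n_i/N
      int r = runif_int(N), g1 = 0;
      while (r >= sizes[g1]) { r -= sizes[g1]; ++g1; }
      // group i2 != i1 with prob n_i/(N - n_{g1})
      r = runif_int(N - sizes[g1]);
      int g2 = 0;
      while (g2 == g1 || r >= sizes[g2]) {
        if (g2 != g1) r -= sizes[g2];
        ++g2;
      }
      int j1 = runif_int(sizes[g1]), j2 = runif_int(sizes[g2]);
      int x1 = members[g1][j1], x2 = members[g2][j2];
      double d12 = D(x1, x2);
      double dW = (G[(size_t)x1 * K + g2] - d12) - G[(size_t)x1 * K + g1]
                + (G[(size_t)x2 * K + g1] - d12) - G[(size_t)x2 * K + g2];
      TSSW += dW;
      TSSB -= dW;
      for (int s = 0; s < N; ++s) {
        double d1 = D(s, x1), d2 = D(s, x2);
        G[(size_t)s * K + g1] += d2 - d1;
        G[(size_t)s * K + g2] += d1 - d2;
      }
      members[g1][j1] = x2; members[g2][j2] = x1;
      lab[x1] = g2; lab[x2] = g1;
    }
    phi_trace[t - 1] = TSSB / TSSW;
    tssb_trace[t - 1] = TSSB;
    tssw_trace[t - 1] = TSSW;
    if (record_labels)
      for (int i = 0; i < N; ++i) labmat(t - 1, i) = lab[i] + 1;
  }
  List out = List::create(_["phi"] = phi_trace, _["tssb"] = tssb_trace,
                          _["tssw"] = tssw_trace);
  if (record_labels) out["labels"] = labmat;
  return out;
}
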