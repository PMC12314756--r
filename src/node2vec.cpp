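// Biased second-order random walks and skip-gram with negative sampling.
// Single-threaded and deterministic given the seed (std::mt19937 throughout,
// independent of R's RNG). The walk bias follows the node2vec scheme: from
// edge (prev -> cur), a neighbour nb of cur is weighted 1/p if nb == prev,
// 1 if nb is adjacent to prev, and 1/q otherwise.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static std::vector<std::vector<int>> as_adj(const List& adj) {
  int n = adj.size();
  std::vector<std::vector<int>> out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    out[i].assign(nb.begin(), nb.end());      // 0-based, sorted by caller
    std::sort(out[i].begin(), out[i].end());
  }
  return out;
}

static inline bool has_edge(const std::vector<std::vector<int>>& adj,
                            int a, int b) {
  const std::vector<int>& v = adj[a];
  return std::binary_search(v.begin(), v.end(), b);
}

// Unnormalized node2vec weights over neighbours of cur given previous vertex
// prev (-1 when the walk has no history yet).
static void step_weights(const std::vector<std::vector<int>>& adj,
                         int prev, int cur, double p, double q,
                         std::vector<double>& w) {
  const std::vector<int>& nb = adj[cur];
  w.resize(nb.size());
  for (size_t i = 0; i < nb.size(); ++i) {
    if (prev < 0) {
      w[i] = 1.0;
    } else if (nb[i] == prev) {
      w[i] = 1.0 / p;
    } else if (has_edge(adj, prev, nb[i])) {
      w[i] = 1.0;
    } else {
      w[i] = 1.0 / q;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_transition_probs(List adj0, int prev0, int cur0,
                                   double p, double q) {
  std::vector<std::vector<int>> adj = as_adj(adj0);
  std::vector<double> w;
  step_weights(adj, prev0, cur0, p, q, w);
  double s = 0.0;
  for (double x : w) s += x;
  NumericVector out(w.size());
  for (size_t i = 0; i < w.size(); ++i) out[i] = (s > 0) ? w[i] / s : 0.0;
  return out;
}

// [[Rcpp::export]]
List cpp_biased_walks(List adj0, double p, double q,
                      int walks_per_node, int walk_length, int seed) {
  std::vector<std::vector<int>> adj = as_adj(adj0);
  int n = adj.size();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  List out(static_cast<R_xlen_t>(n) * walks_per_node);
  std::vector<double> w;
  R_xlen_t pos = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int v = 0; v < n; ++v) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(v);
      int prev = -1, cur = v;
      while ((int)walk.size() < walk_length) {
        const std::vector<int>& nb = adj[cur];
        if (nb.empty()) break;
        step_weights(adj, prev, cur, p, q, w);
        double s = 0.0;
        for (double x : w) s += x;
        double u = unif(rng) * s, acc = 0.0;
        int nxt = nb.back();
        for (size_t i = 0; i < nb.size(); ++i) {
          acc += w[i];
          if (u <= acc) { nxt = nb[i]; break; }
        }
        walk.push_back(nxt);
        prev = cur;
        cur = nxt;
      }
      IntegerVector iv(walk.size());
      for (size_t i = 0; i < walk.size(); ++i) iv[i] = walk[i] + 1; // 1-based
      out[pos++] = iv;
    }
  }
  return out;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
NumericMatrix cpp_skipgram(List walks, int n_vertices, int k, int window,
                           int negative, int epochs, double alpha, int seed) {
  int n_walks = walks.size();
  std::mt19937 rng(static_cast<unsigned int>(seed) + 1u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // corpus frequencies for the unigram^(3/4) negative-sampling distribution
  std::vector<double> cnt(n_vertices, 0.0);
  long long total_tokens = 0;
  for (int wi = 0; wi < n_walks; ++wi) {
    IntegerVector wk = walks[wi];
    if (wk.size() < 2) continue;            // no co-occurrence evidence
    for (int t = 0; t < wk.size(); ++t) cnt[wk[t] - 1] += 1.0;
    total_tokens += wk.size();
  }
  std::vector<double> cum(n_vertices, 0.0);
  double z = 0.0;
  for (int i = 0; i < n_vertices; ++i) {
    z += std::pow(cnt[i], 0.75);
    cum[i] = z;
  }
  if (z <= 0.0) stop("empty walk corpus");

  std::vector<double> syn0((size_t)n_vertices * k), syn1((size_t)n_vertices * k, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif(rng) - 0.5) / k;

  const double alpha_min = alpha * 1e-4;
  long long processed = 0;
  const long long grand_total = (long long)epochs * total_tokens;
  std::vector<double> neu1e(k);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      IntegerVector wk = walks[wi];
      int len = wk.size();
      if (len < 2) continue;
      for (int t = 0; t < len; ++t) {
        ++processed;
        double lr = alpha * (1.0 - (double)processed / (double)(grand_total + 1));
        if (lr < alpha_min) lr = alpha_min;
        int center = wk[t] - 1;
        int b = 1 + (int)(unif(rng) * window);   // reduced window in [1, window]
        if (b > window) b = window;
        for (int j = t - b; j <= t + b; ++j) {
          if (j < 0 || j >= len || j == t) continue;
          int context = wk[j] - 1;
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = context;
              label = 1.0;
            } else {
              double u = unif(rng) * z;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= n_vertices) target = n_vertices - 1;
              if (target == context) continue;
              label = 0.0;
            }
            double* v0 = &syn0[(size_t)center * k];
            double* v1 = &syn1[(size_t)target * k];
            double f = 0.0;
            for (int d2 = 0; d2 < k; ++d2) f += v0[d2] * v1[d2];
            double g = (label - sigmoid(f)) * lr;
            for (int d2 = 0; d2 < k; ++d2) {
              neu1e[d2] += g * v1[d2];
              v1[d2] += g * v0[d2];
            }
          }
          double* v0 = &syn0[(size_t)center * k];
          for (int d2 = 0; d2 < k; ++d2) v0[d2] += neu1e[d2];
        }
      }
    }
  }

  NumericMatrix out(n_vertices, k);
  for (int i = 0; i < n_vertices; ++i) {
    bool seen = cnt[i] > 0.0;
    for (int d = 0; d < k; ++d)
      out(i, d) = seen ? syn0[(size_t)i * k + d] : 0.0;
  }
  return out;
}
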