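#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pairwise mutual information over pre-discretized profiles.
// binmat: genes x samples, entries in 1..B. Returns rows (i, j, mi) for all
// pairs with mi >= threshold (1-based gene indices).
// [[Rcpp::export(name = "mi_pairs_above")]]
NumericMatrix mi_pairs_above(IntegerMatrix binmat, int B, double threshold) {
  const int G = binmat.nrow(), n = binmat.ncol();
  std::vector<std::vector<int>> bins(G, std::vector<int>(n));
  std::vector<std::vector<int>> marg(G, std::vector<int>(B, 0));
  for (int g = 0; g < G; ++g) {
    for (int s = 0; s < n; ++s) {
      int b = binmat(g, s) - 1;
      bins[g][s] = b;
      marg[g][b]++;
    }
  }
  std::vector<double> out;
  std::vector<int> joint(B * B);
  const double ln_n = std::log((double)n);
  for (int i = 0; i < G; ++i) {
    for (int j = i + 1; j < G; ++j) {
      std::fill(joint.begin(), joint.end(), 0);
      for (int s = 0; s < n; ++s) joint[bins[i][s] * B + bins[j][s]]++;
      double mi = 0.0;
      for (int a = 0; a < B; ++a) {
        if (marg[i][a] == 0) continue;
        for (int b = 0; b < B; ++b) {
          int c = joint[a * B + b];
          if (c == 0 || marg[j][b] == 0) continue;
          double pij = (double)c / n;
          mi += pij * (std::log((double)c) + ln_n -
                       std::log((double)marg[i][a]) -
                       std::log((double)marg[j][b]));
        }
      }
      if (mi >= threshold) {
        out.push_back(i + 1);
        out.push_back(j + 1);
        out.push_back(mi);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  int m = out.size() / 3;
  NumericMatrix res(m, 3);
  for (int r = 0; r < m; ++r) {
    res(r, 0) = out[3 * r];
    res(r, 1) = out[3 * r + 1];
    res(r, 2) = out[3 * r + 2];
  }
  return res;
}

// Score of an active-node state: sum of the top n_modules calibrated
// component scores sA = (sum(z)/sqrt(k) - mu[k]) / sigma[k].
static double state_score(const std::vector<char> &active,
                          const std::vector<int> &ptr,
                          const std::vector<int> &idx,
                          const NumericVector &z,
                          const NumericVector &mu,
                          const NumericVector &sigma,
                          int n_modules,
                          std::vector<int> &comp_mark, int &mark_gen,
                          std::vector<int> &stack,
                          std::vector<double> &scores) {
  const int N = active.size();
  ++mark_gen;
  scores.clear();
  for (int v = 0; v < N; ++v) {
    if (!active[v] || comp_mark[v] == mark_gen) continue;
    double zsum = 0.0;
    int k = 0;
    stack.clear();
    stack.push_back(v);
    comp_mark[v] = mark_gen;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      zsum += z[u];
      ++k;
      for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
        int w = idx[e];
        if (active[w] && comp_mark[w] != mark_gen) {
          comp_mark[w] = mark_gen;
          stack.push_back(w);
        }
      }
    }
    double sa = 0.0;
    if (sigma[k] > 0.0) sa = (zsum / std::sqrt((double)k) - mu[k]) / sigma[k];
    scores.push_back(sa);
  }
  if (scores.empty()) return 0.0;
  int take = std::min((int)scores.size(), n_modules);
  std::partial_sort(scores.begin(), scores.begin() + take, scores.end(),
                    std::greater<double>());
  double total = 0.0;
  for (int i = 0; i < take; ++i) total += scores[i];
  return total;
}

// Simulated-annealing search for high-scoring active subnetworks.
// csr_ptr/csr_idx: 0-based CSR adjacency; z: per-node z-scores;
// mu/sigma: calibration moments indexed by component size (length N + 1).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = "sa_search_cpp")]]
List sa_search_cpp(IntegerVector csr_ptr, IntegerVector csr_idx,
                   NumericVector z, NumericVector mu, NumericVector sigma,
                   int n_modules, double start_temp, double end_temp,
                   int iterations) {
  const int N = z.size();
  std::vector<int> ptr(csr_ptr.begin(), csr_ptr.end());
  std::vector<int> idx(csr_idx.begin(), csr_idx.end());
  std::vector<char> active(N), best(N);
  for (int v = 0; v < N; ++v) active[v] = (unif_rand() < 0.5) ? 1 : 0;

  std::vector<int> comp_mark(N, 0), stack;
  std::vector<double> scores;
  int mark_gen = 0;
  stack.reserve(N);

  double cur = state_score(active, ptr, idx, z, mu, sigma, n_modules,
                           comp_mark, mark_gen, stack, scores);
  double best_score = cur;
  best = active;

  const double cool = (iterations > 0)
    ? std::pow(end_temp / start_temp, 1.0 / iterations) : 1.0;
  double temp = start_temp;
  for (int it = 0; it < iterations; ++it) {
    temp *= cool;
    int v = (int)(unif_rand() * N);
    if (v >= N) v = N - 1;
    active[v] ^= 1;
    double prop = state_score(active, ptr, idx, z, mu, sigma, n_modules,
                              comp_mark, mark_gen, stack, scores);
    double delta = prop - cur;
    if (delta > 0 || unif_rand() < std::exp(delta / temp)) {
      cur = prop;
      if (cur > best_score) {
        best_score = cur;
        best = active;
      }
    } else {
      active[v] ^= 1; // reject
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  LogicalVector best_out(N);
  for (int v = 0; v < N; ++v) best_out[v] = best[v] != 0;
  return List::create(_["active"] = best_out, _["score"] = best_score);
}
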