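#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Distances between a permutation (perm[r] = item at rank r, 0-based) and a
// reference list given as item -> position lookup (pos[item] = rank).

static double footrule(const std::vector<int>& perm_pos, const int* list_pos,
                       int k) {
  double d = 0.0;
  for (int i = 0; i < k; ++i) d += std::abs(perm_pos[i] - list_pos[i]);
  return d;
}

static double kendall(const std::vector<int>& perm_pos, const int* list_pos,
                      int k) {
  // number of discordant item pairs; O(k^2), k is small here
  double d = 0.0;
  for (int i = 0; i < k - 1; ++i)
    for (int j = i + 1; j < k; ++j) {
      int a = perm_pos[i] - perm_pos[j];
      int b = list_pos[i] - list_pos[j];
      if ((a < 0 && b > 0) || (a > 0 && b < 0)) d += 1.0;
    }
  return d;
}

// Weighted objective Phi of a permutation against all lists.
// lists_pos: k x L column-major (position of item i in list l).
static double phi_of(const std::vector<int>& perm, const IntegerMatrix& lists_pos,
                     const NumericVector& weights, int metric) {
  int k = perm.size(), L = lists_pos.ncol();
  std::vector<int> perm_pos(k);
  for (int r = 0; r < k; ++r) perm_pos[perm[r]] = r;
  double phi = 0.0;
  for (int l = 0; l < L; ++l) {
    const int* lp = &lists_pos(0, l);
    double d = (metric == 0) ? footrule(perm_pos, lp, k)
                             : kendall(perm_pos, lp, k);
    phi += weights[l] * d;
  }
  return phi;
}

// Exact minimizer by exhaustive enumeration in lexicographic order; the
// first strict improvement wins, so ties resolve to the lexicographically
// smallest permutation. k <= 8 (8! = 40320).
// [[Rcpp::export]]
List brute_force_consensus(IntegerMatrix lists_pos, NumericVector weights,
                           int metric) {
  int k = lists_pos.nrow();
  if (k > 8) stop("brute force limited to k <= 8");
  std::vector<int> perm(k);
  std::iota(perm.begin(), perm.end(), 0);
  std::vector<int> best = perm;
  double best_phi = phi_of(perm, lists_pos, weights, metric);
  while (std::next_permutation(perm.begin(), perm.end())) {
    double p = phi_of(perm, lists_pos, weights, metric);
    if (p < best_phi) { best_phi = p; best = perm; }
  }
  return List::create(_["perm"] = IntegerVector(best.begin(), best.end()),
                      _["phi"] = best_phi);
}

// Cross-entropy Monte-Carlo minimizer over a k x k item-position
// probability matrix. Permutations are sampled position by position with
// renormalization over the items still unplaced; the elite fraction
// updates the matrix with multiplicative smoothing. Uses R's RNG so the
// result is reproducible under set.seed().
// [[Rcpp::export]]
List ce_consensus(IntegerMatrix lists_pos, NumericVector weights, int metric,
                  int N, double rho, double smoothing_w, int max_iter,
                  int convergence_window) {
  int k = lists_pos.nrow();
  if (k < 2) stop("need k >= 2");
  int n_elite = (int)std::ceil(rho * N);
  if (n_elite < 1) n_elite = 1;
  std::vector<double> P(k * k, 1.0 / k);  // P[item + k*pos]
  std::vector<int> best;
  double best_phi = R_PosInf;
  int stall = 0, iter = 0;
  bool converged = false;
  std::vector<std::vector<int>> samples(N, std::vector<int>(k));
  std::vector<double> phis(N);
  std::vector<int> order(N);
  RNGScope scope;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (int s = 0; s < N; ++s) {
      std::vector<bool> used(k, false);
      std::vector<int>& perm = samples[s];
      for (int pos = 0; pos < k; ++pos) {
        double tot = 0.0;
        for (int i = 0; i < k; ++i)
          if (!used[i]) tot += P[i + k * pos];
        double u = unif_rand() * tot;
        int chosen = -1;
        for (int i = 0; i < k; ++i) {
          if (used[i]) continue;
          u -= P[i + k * pos];
          chosen = i;
          if (u <= 0) break;
        }
        used[chosen] = true;
        perm[pos] = chosen;
      }
      phis[s] = phi_of(perm, lists_pos, weights, metric);
    }
    std::iota(order.begin(), order.end(), 0);
    std::nth_element(order.begin(), order.begin() + n_elite - 1, order.end(),
                     [&](int a, int b) { return phis[a] < phis[b]; });
    double iter_best = R_PosInf;
    int iter_best_idx = 0;
    for (int s = 0; s < N; ++s)
      if (phis[s] < iter_best) { iter_best = phis[s]; iter_best_idx = s; }
    if (iter_best < best_phi) {
      best_phi = iter_best;
      best = samples[iter_best_idx];
      stall = 0;
    } else {
      ++stall;
    }
    std::vector<double> freq(k * k, 0.0);
    for (int e = 0; e < n_elite; ++e) {
      const std::vector<int>& perm = samples[order[e]];
      for (int pos = 0; pos < k; ++pos)
        freq[perm[pos] + k * pos] += 1.0 / n_elite;
    }
    for (int i = 0; i < k * k; ++i)
      P[i] = smoothing_w * freq[i] + (1.0 - smoothing_w) * P[i];
    if (stall >= convergence_window) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(_["perm"] = IntegerVector(best.begin(), best.end()),
                      _["phi"] = best_phi, _["iterations"] = iter,
                      _["converged"] = converged);
}
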