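// Permutation search for sorting HMM states: maximize
//   sum_{j,i} B[perm[j], perm[i]] * F[j, i]
// with F_ji = -log((i-j)^2) above the diagonal and 0 elsewhere, so transition
// mass is pushed just above the diagonal. Exhaustive enumeration for small K,
// otherwise seeded restarts of greedy insertion + pairwise-swap hill climbing
// with O(K) delta evaluation.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double perm_obj(const arma::mat& B, const arma::mat& F,
                       const std::vector<int>& p) {
  const int K = p.size();
  double s = 0.0;
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i)
      if (F(j, i) != 0.0) s += B(p[j], p[i]) * F(j, i);
  return s;
}

// [[Rcpp::export]]
double perm_objective_cpp(const arma::mat& B, const arma::mat& F,
                          const IntegerVector& perm) {
  std::vector<int> p(perm.size());
  for (int i = 0; i < perm.size(); ++i) p[i] = perm[i] - 1;
  return perm_obj(B, F, p);
}

// contribution of all terms whose row or column position is a or b
static double contrib_ab(const arma::mat& B, const arma::mat& F,
                         const std::vector<int>& p, int a, int b) {
  const int K = p.size();
  double s = 0.0;
  for (int i = 0; i < K; ++i) {
    s += B(p[a], p[i]) * F(a, i) + B(p[b], p[i]) * F(b, i);
    if (i != a && i != b)
      s += B(p[i], p[a]) * F(i, a) + B(p[i], p[b]) * F(i, b);
  }
  return s;
}

static void hill_climb(const arma::mat& B, const arma::mat& F,
                       std::vector<int>& p, double& obj) {
  const int K = p.size();
  bool improved = true;
  int sweeps = 0;
  while (improved && sweeps < 200) {
    improved = false;
    ++sweeps;
    for (int a = 0; a < K - 1; ++a) {
      for (int b = a + 1; b < K; ++b) {
        double before = contrib_ab(B, F, p, a, b);
        std::swap(p[a], p[b]);
        double after = contrib_ab(B, F, p, a, b);
        if (after > before + 1e-12) {
          obj += after - before;
          improved = true;
        } else {
          std::swap(p[a], p[b]);
        }
      }
    }
  }
}

// greedy insertion construction from a given state order
static std::vector<int> greedy_insert(const arma::mat& B, const arma::mat& F,
                                      const std::vector<int>& order) {
  std::vector<int> p;
  for (int s : order) {
    int bestPos = 0;
    double bestVal = -arma::datum::inf;
    for (size_t pos = 0; pos <= p.size(); ++pos) {
      std::vector<int> q(p);
      q.insert(q.begin() + pos, s);
      // partial objective with F restricted to the current positions
      double v = 0.0;
      for (size_t j = 0; j < q.size(); ++j)
        for (size_t i = 0; i < q.size(); ++i)
          if (F(j, i) != 0.0) v += B(q[j], q[i]) * F(j, i);
      if (v > bestVal) { bestVal = v; bestPos = pos; }
    }
    p.insert(p.begin() + bestPos, s);
  }
  return p;
}

// [[Rcpp::export]]
List sort_states_cpp(const arma::mat& B, const arma::mat& F, int restarts,
                     int seed) {
  const int K = B.n_rows;
  std::vector<int> best(K);
  for (int i = 0; i < K; ++i) best[i] = i;
  double bestObj = perm_obj(B, F, best);

  if (K <= 8) {  // exact enumeration, first optimum in lexicographic order
    std::vector<int> p(K);
    for (int i = 0; i < K; ++i) p[i] = i;
    do {
      double v = perm_obj(B, F, p);
      if (v > bestObj + 1e-12) { bestObj = v; best = p; }
    } while (std::next_permutation(p.begin(), p.end()));
    IntegerVector out(K);
    for (int i = 0; i < K; ++i) out[i] = best[i] + 1;
    return List::create(_["perm"] = out, _["objective"] = bestObj,
                        _["exact"] = true);
  }

  std::mt19937 rng(static_cast<unsigned>(seed));
  {  // greedy insertion from the identity order, then polish
    std::vector<int> order(K);
    for (int i = 0; i < K; ++i) order[i] = i;
    std::vector<int> p = greedy_insert(B, F, order);
    double obj = perm_obj(B, F, p);
    hill_climb(B, F, p, obj);
    if (obj > bestObj) { bestObj = obj; best = p; }
  }
  for (int r = 0; r < restarts; ++r) {
    std::vector<int> p(K);
    for (int i = 0; i < K; ++i) p[i] = i;
    std::shuffle(p.begin(), p.end(), rng);
    if (r % 2 == 1) p = greedy_insert(B, F, p);
    double obj = perm_obj(B, F, p);
    hill_climb(B, F, p, obj);
    if (obj > bestObj + 1e-12) { bestObj = obj; best = p; }
  }
  IntegerVector out(K);
  for (int i = 0; i < K; ++i) out[i] = best[i] + 1;
  return List::create(_["perm"] = out, _["objective"] = bestObj,
                      _["exact"] = false);
}
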