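#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inner Metropolis loop for the SARF annealer. Permutations are 0-based
// here; the R wrapper translates. SARF changes are applied as O(1) deltas
// (a swap touches at most four adjacencies, a block reversal only its two
// boundary adjacencies since D is symmetric).

static inline double sarf_full(const NumericMatrix& d, const std::vector<int>& p) {
  double s = 0.0;
  for (size_t i = 0; i + 1 < p.size(); ++i) s += d(p[i], p[i + 1]);
  return s;
}

// [[Rcpp::export]]
List sa_core(NumericMatrix d, IntegerVector perm0, double A, int m, int L,
             int schedule, double alpha, int neighborhood, int patience,
             int thin) {
  const int k = d.nrow();
  std::vector<int> cur(perm0.begin(), perm0.end());
  std::vector<int> best(cur);
  double f_cur = sarf_full(d, cur);
  double f_best = f_cur;

  long total = (long)(m + 1) * L;
  std::vector<double> tr_iter, tr_temp, tr_cur, tr_best;
  if (thin > 0) {
    tr_iter.reserve(total / thin + 2);
    tr_temp.reserve(total / thin + 2);
    tr_cur.reserve(total / thin + 2);
    tr_best.reserve(total / thin + 2);
  }

  long accepted = 0, iter = 0;
  int stale = 0;
  double last_c = A;

  for (int n = 0; n <= m; ++n) {
    double c;
    if (schedule == 0)      c = A * (1.0 - (double)n / (m + 1.0));
    else if (schedule == 1) c = A * std::pow(alpha, n);
    else                    c = A / std::log(n + M_E);
    last_c = c;

    bool improved = false;
    for (int i = 0; i < L; ++i) {
      ++iter;
      double delta;
      int p = 0, q = 0;
      bool is_swap = (neighborhood == 0);
      // uniform unordered pair of positions p < q
      p = (int)(unif_rand() * k); if (p == k) p = k - 1;
      q = (int)(unif_rand() * (k - 1)); if (q == k - 1) q = k - 2;
      if (q >= p) ++q;
      if (p > q) std::swap(p, q);

      if (is_swap) {
        int a = cur[p], b = cur[q];
        delta = 0.0;
        if (q == p + 1) {
          if (p > 0)     delta += d(cur[p - 1], b) - d(cur[p - 1], a);
          if (q < k - 1) delta += d(a, cur[q + 1]) - d(b, cur[q + 1]);
        } else {
          if (p > 0)     delta += d(cur[p - 1], b) - d(cur[p - 1], a);
          delta += d(b, cur[p + 1]) - d(a, cur[p + 1]);
          delta += d(cur[q - 1], a) - d(cur[q - 1], b);
          if (q < k - 1) delta += d(a, cur[q + 1]) - d(b, cur[q + 1]);
        }
      } else { // reverse block [p..q]
        delta = 0.0;
        if (p > 0)     delta += d(cur[p - 1], cur[q]) - d(cur[p - 1], cur[p]);
        if (q < k - 1) delta += d(cur[p], cur[q + 1]) - d(cur[q], cur[q + 1]);
      }

      bool accept = (delta <= 0.0) || (unif_rand() < std::exp(-delta / c));
      if (accept) {
        if (is_swap) std::swap(cur[p], cur[q]);
        else std::reverse(cur.begin() + p, cur.begin() + q + 1);
        f_cur += delta;
        ++accepted;
        if (f_cur < f_best - 1e-12) {
          f_best = f_cur;
          best = cur;
          improved = true;
        }
      }
      if (thin > 0 && (iter % thin == 0)) {
        tr_iter.push_back((double)iter);
        tr_temp.push_back(c);
        tr_cur.push_back(f_cur);
        tr_best.push_back(f_best);
      }
    }
    stale = improved ? 0 : stale + 1;
    if (stale >= patience) break;
  }
  if (thin > 0 && (tr_iter.empty() || tr_iter.back() != (double)iter)) {
    tr_iter.push_back((double)iter);
    tr_temp.push_back(last_c);
    tr_cur.push_back(f_cur);
    tr_best.push_back(f_best);
  }

  return List::create(
    _["best_perm"] = IntegerVector(best.begin(), best.end()),
    _["best_sarf"] = f_best,
    _["accepted"] = (double)accepted,
    _["evaluations"] = (double)iter,
    _["traj_iter"] = NumericVector(tr_iter.begin(), tr_iter.end()),
    _["traj_temp"] = NumericVector(tr_temp.begin(), tr_temp.end()),
    _["traj_cur"] = NumericVector(tr_cur.begin(), tr_cur.end()),
    _["traj_best"] = NumericVector(tr_best.begin(), tr_best.end()));
}
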