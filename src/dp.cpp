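#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Circular-path dynamic programme over a polar cost grid.
//
// Finds the radial index path p[0..na-1] minimising
//   sum_i cost(i, p[i]) + lambda * sum_i (p[i+1] - p[i])^2
// subject to |p[i+1] - p[i]| <= delta for every i, including the wrap pair
// p[na-1] -> p[0]. Exact wrap closure: the DP is run once per candidate
// start radius and the best wrap-consistent solution is kept. Ties are
// broken toward the smaller total radius (sum of 1-based radial indices),
// then the smaller start radius.
//
// cost: na x nr matrix (rows = angles, cols = radial samples); +Inf entries
// are forbidden samples. Returns path as 1-based radial indices, the
// objective, and a `lost` flag when no finite wrap-consistent path exists.
// [[Rcpp::export(name = ".dp_circular_cpp")]]
List dp_circular_cpp(NumericMatrix cost, int delta, double lambda) {
  const int na = cost.nrow(), nr = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  if (delta < 1) stop("delta must be >= 1");

  std::vector<double> M(nr), Mn(nr);     // best cost to (angle i, radius r)
  std::vector<double> S(nr), Sn(nr);     // radius-sum tie-break tracker
  std::vector<int> bp(static_cast<size_t>(na) * nr);

  double best_obj = INF, best_sum = INF;
  int best_start = -1;
  std::vector<int> best_path(na), path(na);

  for (int s = 0; s < nr; ++s) {
    if (!R_finite(cost(0, s))) continue;
    for (int r = 0; r < nr; ++r) { M[r] = INF; S[r] = INF; }
    M[s] = cost(0, s);
    S[s] = s + 1;
    for (int i = 1; i < na; ++i) {
      for (int r = 0; r < nr; ++r) {
        double bc = INF, bs = INF;
        int bprev = -1;
        if (R_finite(cost(i, r))) {
          const int lo = std::max(0, r - delta), hi = std::min(nr - 1, r + delta);
          for (int rp = lo; rp <= hi; ++rp) {
            if (!R_finite(M[rp])) continue;
            const double dr = r - rp;
            const double c = M[rp] + lambda * dr * dr + cost(i, r);
            const double sum = S[rp] + (r + 1);
            if (c < bc || (c == bc && sum < bs)) {
              bc = c; bs = sum; bprev = rp;
            }
          }
        }
        Mn[r] = bc; Sn[r] = bs;
        bp[static_cast<size_t>(i) * nr + r] = bprev;
      }
      M.swap(Mn); S.swap(Sn);
    }
    // close the wrap: last radius must be within delta of the start s
    const int lo = std::max(0, s - delta), hi = std::min(nr - 1, s + delta);
    double obj = INF, osum = INF;
    int rend = -1;
    for (int r = lo; r <= hi; ++r) {
      if (!R_finite(M[r])) continue;
      const double dr = s - r;
      const double c = M[r] + (na > 1 ? lambda * dr * dr : 0.0);
      if (c < obj || (c == obj && S[r] < osum)) {
        obj = c; osum = S[r]; rend = r;
      }
    }
    if (rend < 0) continue;
    if (obj < best_obj || (obj == best_obj && osum < best_sum)) {
      // backtrack this start's path
      int r = rend;
      for (int i = na - 1; i >= 1; --i) {
        path[i] = r;
        r = bp[static_cast<size_t>(i) * nr + r];
      }
      path[0] = r;  // == s by construction
      best_obj = obj; best_sum = osum; best_start = s;
      best_path = path;
    }
  }

  if (best_start < 0)
    return List::create(_["path"] = IntegerVector(0),
                        _["objective"] = NA_REAL, _["lost"] = true);
  IntegerVector out(na);
  for (int i = 0; i < na; ++i) out[i] = best_path[i] + 1;
  return List::create(_["path"] = out, _["objective"] = best_obj,
                      _["lost"] = false);
}
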