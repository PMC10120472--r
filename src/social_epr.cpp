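#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequential Social-EPR visit dynamics for a single user.
//
// At each visit occasion the user explores a new place with probability
// min(1, rho * S^-gamma), where S is the number of distinct places already
// visited (forced exploration at S = 0); otherwise they return to a known
// place with probability proportional to its past visit count. An
// exploration is "social" with probability sigma_s: the candidate pool is
// the POIs whose dominant income quantile differs from the user's;
// otherwise the same-quantile pool. Candidates are drawn proportionally to
// precomputed weights (distance kernel x subcategory preference),
// excluding places already visited. An exhausted pool falls back to the
// complementary pool (counted); with every place visited the occasion
// becomes a preferential return.
//
// Uses R's RNG so set.seed() in R controls the stream.
//
// cum_same / cum_other: cumulative weights over the two pools;
// idx_same / idx_other: 1-based global POI indices aligned with them;
// w_all: raw weight per global POI; set_of_poi: 1 = same pool, 2 = other.
// [[Rcpp::export]]
List simulate_user_seq(int n_events,
                       NumericVector cum_same, IntegerVector idx_same,
                       NumericVector cum_other, IntegerVector idx_other,
                       NumericVector w_all, IntegerVector set_of_poi,
                       double rho, double gamma, double sigma_s) {
  int n_poi = w_all.size();
  IntegerVector out_poi(n_events);
  LogicalVector out_explore(n_events);
  int n_fallback = 0;

  std::vector<char> visited(n_poi, 0);
  std::vector<int> hist_poi;    // distinct visited places (1-based)
  std::vector<int> hist_cnt;    // their visit counts
  hist_poi.reserve(256);
  hist_cnt.reserve(256);
  long total_visits = 0;

  double tot_same = cum_same.size() ? cum_same[cum_same.size() - 1] : 0.0;
  double tot_other = cum_other.size() ? cum_other[cum_other.size() - 1] : 0.0;
  double vis_same = 0.0, vis_other = 0.0;  // weight already visited per pool
  const double eps = 1e-12;

  // draw an unvisited POI from one pool; returns 1-based global index or 0
  auto draw_from = [&](const NumericVector& cum, const IntegerVector& idx,
                       double total, double visited_w) -> int {
    double remaining = total - visited_w;
    if (remaining <= eps || idx.size() == 0) return 0;
    // rejection with binary search; falls back to an exact linear scan
    for (int tries = 0; tries < 50; ++tries) {
      double u = unif_rand() * total;
      int lo = 0, hi = cum.size() - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      int g = idx[lo];
      if (!visited[g - 1]) return g;
    }
    double target = unif_rand() * remaining, acc = 0.0;
    for (int k = 0; k < idx.size(); ++k) {
      int g = idx[k];
      if (visited[g - 1]) continue;
      acc += w_all[g - 1];
      if (acc >= target) return g;
    }
    for (int k = idx.size() - 1; k >= 0; --k)  // numerical guard
      if (!visited[idx[k] - 1]) return idx[k];
    return 0;
  };

  for (int e = 0; e < n_events; ++e) {
    int S = (int)hist_poi.size();
    bool explore;
    if (S == 0) {
      explore = true;
    } else {
      double p = rho * std::pow((double)S, -gamma);
      if (p > 1.0) p = 1.0;
      explore = (unif_rand() < p);
    }
    if (explore && S >= n_poi) explore = false;  // every place known

    int chosen = 0;
    if (explore) {
      bool social = (unif_rand() < sigma_s);
      if (social) {
        chosen = draw_from(cum_other, idx_other, tot_other, vis_other);
        if (chosen == 0) {
          chosen = draw_from(cum_same, idx_same, tot_same, vis_same);
          if (chosen != 0) ++n_fallback;
        }
      } else {
        chosen = draw_from(cum_same, idx_same, tot_same, vis_same);
        if (chosen == 0) {
          chosen = draw_from(cum_other, idx_other, tot_other, vis_other);
          if (chosen != 0) ++n_fallback;
        }
      }
      if (chosen == 0) {
        if (S == 0) stop("no candidate POIs with positive weight for this user");
        explore = false;  // both pools exhausted: return instead
      }
    }

    if (explore) {
      visited[chosen - 1] = 1;
      if (set_of_poi[chosen - 1] == 1) vis_same += w_all[chosen - 1];
      else vis_other += w_all[chosen - 1];
      hist_poi.push_back(chosen);
      hist_cnt.push_back(1);
    } else {
      double target = unif_rand() * (double)total_visits;
      double acc = 0.0;
      int pick = (int)hist_poi.size() - 1;
      for (size_t k = 0; k < hist_poi.size(); ++k) {
        acc += (double)hist_cnt[k];
        if (acc >= target) { pick = (int)k; break; }
      }
      chosen = hist_poi[pick];
      hist_cnt[pick] += 1;
    }
    ++total_visits;
    out_poi[e] = chosen;
    out_explore[e] = explore;
  }

  return List::create(_["poi"] = out_poi, _["explore"] = out_explore,
                      _["n_fallback"] = n_fallback);
}
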