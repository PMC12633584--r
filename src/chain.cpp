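#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Co-linear chaining DP over items in tree order. Items may be seeds or
// fragments; each has a read interval [start, end) and a base score (its
// covered read bases). A transition i -> j is admissible when start[i] <
// start[j], the graph distance is finite, and the gap g = |read_gap -
// graph_gap| passes the pass-specific rule. The score recurrence is
//   score[j] = base[j] + max(0, max_i score[i] - overlap(i,j) - cost(i,j))
// with overlap(i,j) = max(0, end[i] - start[j]) trimming read bases counted
// twice, so a chain's score is its covered read bases minus gap costs.
// [[Rcpp::export(name = ".chain_dp_cpp")]]
List chain_dp_cpp(NumericVector start, NumericVector end, NumericVector base,
                  IntegerVector ci, IntegerVector cj, NumericVector gd,
                  double a, double b, double max_gap, bool exact_only) {
  int n = start.size();
  NumericVector score(n);
  IntegerVector parent(n, -1);
  for (int j = 0; j < n; ++j) score[j] = base[j];
  // transitions are assumed grouped by j ascending
  for (int t = 0; t < ci.size(); ++t) {
    int i = ci[t], j = cj[t];
    double g_dist = gd[t];
    if (!R_finite(g_dist)) continue;
    if (!(start[i] < start[j])) continue;
    double read_gap = start[j] - start[i];
    double g = std::fabs(read_gap - g_dist);
    double cost;
    if (exact_only) {
      if (g != 0 || read_gap > max_gap) continue;
      cost = 0;
    } else {
      if (read_gap > max_gap || g_dist > max_gap || g > max_gap) continue;
      cost = (g == 0) ? 0 : a * g + b * std::log2(g);
    }
    double overlap = std::max(0.0, end[i] - start[j]);
    double cand = score[i] - overlap - cost + base[j];
    if (cand > score[j] + 1e-12 ||
        (std::fabs(cand - score[j]) <= 1e-12 && parent[j] >= 0 && i < parent[j])) {
      score[j] = cand;
      parent[j] = i;
    }
  }
  return List::create(_["score"] = score, _["parent"] = parent);
}
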