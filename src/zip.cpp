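#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Pairwise seed distance from zip-code level tables.
//
// Each seed carries one row per snarl-tree level, root chain first:
//   col 0 kind (0 = node item, 1 = snarl gap)
//   col 1 chain id
//   col 2 item index (node item or gap index within the chain)
//   col 3 descending child chain id (gaps; -1 for node items)
//   col 4 lo, col 5 hi  (absolute chain coordinates of the item interval)
//   col 6 FSf, 7 TEf, 8 FSr, 9 TEr (interval-relative distances for
//         forward / reverse traversal of the chain; Inf = infeasible)
//
// The distance from s to t (s before t in tree order, traversal `dir`,
// 0 = chain-forward, 1 = chain-reverse) is resolved at the deepest level
// where the two zip codes diverge. Finite results always correspond to a
// real walk, so on cyclic or inverted regions the value may exceed, but
// never under-report, the true minimum distance.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".zip_pair_dist_cpp")]]
NumericVector zip_pair_dist_cpp(NumericMatrix levels, IntegerVector ptr,
                                IntegerVector depth, IntegerVector ia,
                                IntegerVector ib, int dir) {
  int npair = ia.size();
  NumericVector out(npair);
  for (int p = 0; p < npair; ++p) {
    int sa = ptr[ia[p] - 1] - 1, sb = ptr[ib[p] - 1] - 1;
    int da = depth[ia[p] - 1], db = depth[ib[p] - 1];
    int m = std::min(da, db);
    double d = INF;
    for (int l = 0; l < m; ++l) {
      int ra = sa + l, rb = sb + l;
      if (levels(ra, 1) != levels(rb, 1)) { d = INF; break; }  // different chain
      bool same_item = levels(ra, 0) == levels(rb, 0) &&
                       levels(ra, 2) == levels(rb, 2);
      if (same_item) {
        if (levels(ra, 0) == 0) {  // same node
          if (dir == 0) {
            double fa = levels(ra, 6), fb = levels(rb, 6);
            d = (fa < INF && fb < INF && fb >= fa) ? fb - fa : INF;
          } else {
            double fa = levels(ra, 8), fb = levels(rb, 8);
            d = (fa < INF && fb < INF && fb >= fa) ? fb - fa : INF;
          }
          break;
        }
        // same gap: same descending chain -> resolve deeper; else siblings
        if (levels(ra, 3) != levels(rb, 3)) { d = INF; break; }
        continue;
      }
      // different items of a common chain
      if (dir == 0) {
        if (levels(rb, 4) >= levels(ra, 5))
          d = levels(ra, 7) + (levels(rb, 4) - levels(ra, 5)) + levels(rb, 6);
        else d = INF;
      } else {
        if (levels(ra, 4) >= levels(rb, 5))
          d = levels(ra, 9) + (levels(ra, 4) - levels(rb, 5)) + levels(rb, 8);
        else d = INF;
      }
      break;
    }
    out[p] = d;
  }
  return out;
}
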