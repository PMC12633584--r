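#include <Rcpp.h>
#include <vector>
#include <queue>
#include <map>
#include <limits>
using namespace Rcpp;

// Directed traversal vertices: v = 2*(node-1) + dir, dir 0 = forward
// (entered via the left side, exits via the right face), dir 1 = reverse.
// Distances are in base steps: dist[v] = number of bases strictly between a
// source OUT point (just past a node's last traversed base) and the first
// base of v. Passing through a node costs its length.

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct DirGraph {
  int n;
  std::vector<int> node_len;
  // adjacency from a face (side vertex) to directed vertices entered
  std::vector<std::vector<int>> face_adj;  // indexed by 2*(node-1)+side
  void build(int n_nodes, const IntegerVector& len, const IntegerMatrix& edges) {
    n = n_nodes;
    node_len.assign(len.begin(), len.end());
    face_adj.assign(2 * n, {});
    for (int i = 0; i < edges.nrow(); ++i) {
      int an = edges(i, 0) - 1, as = edges(i, 1);
      int bn = edges(i, 2) - 1, bs = edges(i, 3);
      // leaving a via face as enters b via face bs (and vice versa)
      face_adj[2 * an + as].push_back(2 * bn + (bs == 0 ? 0 : 1));
      face_adj[2 * bn + bs].push_back(2 * an + (as == 0 ? 0 : 1));
    }
  }
  int exit_face(int v) const {   // face used when leaving directed vertex v
    int node = v >> 1, dir = v & 1;
    return 2 * node + (dir == 0 ? 1 : 0);
  }
};

// Dijkstra from the OUT point at `src_face`; if `allowed` non-empty, paths
// may only pass *through* nodes flagged allowed (arrival anywhere is fine).
std::vector<double> dijkstra_from_face(const DirGraph& g, int src_face,
                                       const std::vector<char>& allowed) {
  std::vector<double> dist(2 * g.n, INF);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (int w : g.face_adj[src_face]) {
    if (dist[w] > 0) { dist[w] = 0; pq.push({0, w}); }
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int v = top.second;
    if (d > dist[v]) continue;
    int node = v >> 1;
    if (!allowed.empty() && !allowed[node]) continue;  // cannot pass through
    double nd = d + g.node_len[node];
    for (int w : g.face_adj[g.exit_face(v)]) {
      if (nd < dist[w]) { dist[w] = nd; pq.push({nd, w}); }
    }
  }
  return dist;
}

}  // namespace

// Batched exact minimum-distance queries. a and b are k x 3 matrices of
// (node, orient, offset) with orient 0 = forward, offsets 0-based in
// traversal orientation.
// [[Rcpp::export(name = ".min_distance_cpp")]]
NumericVector min_distance_cpp(int n_nodes, IntegerVector node_len,
                               IntegerMatrix edges, IntegerMatrix a,
                               IntegerMatrix b) {
  DirGraph g; g.build(n_nodes, node_len, edges);
  std::vector<char> no_restrict;
  int k = a.nrow();
  NumericVector out(k);
  std::map<int, std::vector<double>> cache;  // source directed vertex -> dist
  for (int i = 0; i < k; ++i) {
    int an = a(i, 0), ao = a(i, 1), af = a(i, 2);
    int bn = b(i, 0), bo = b(i, 1), bf = b(i, 2);
    int va = 2 * (an - 1) + ao, vb = 2 * (bn - 1) + bo;
    double best = INF;
    if (va == vb && bf >= af) best = bf - af;
    auto it = cache.find(va);
    if (it == cache.end()) {
      it = cache.emplace(va, dijkstra_from_face(g, g.exit_face(va),
                                                no_restrict)).first;
    }
    double through = it->second[vb];
    if (through < INF) {
      double cand = (node_len[an - 1] - af) + through + bf;
      if (cand < best) best = cand;
    }
    out[i] = best;
  }
  return out;
}

// Restricted distances used for snarl boundary tables: from the OUT point
// of `src_face` (1-based node, side), passing only through `allowed`
// nodes, to the IN point of every directed vertex. Returns length-2n vector.
// [[Rcpp::export(name = ".restricted_dist_cpp")]]
NumericVector restricted_dist_cpp(int n_nodes, IntegerVector node_len,
                                  IntegerMatrix edges, int src_node,
                                  int src_side, IntegerVector allowed_nodes) {
  DirGraph g; g.build(n_nodes, node_len, edges);
  std::vector<char> allowed(n_nodes, 0);
  for (int i = 0; i < allowed_nodes.size(); ++i)
    allowed[allowed_nodes[i] - 1] = 1;
  std::vector<double> d = dijkstra_from_face(
      g, 2 * (src_node - 1) + src_side, allowed);
  return NumericVector(d.begin(), d.end());
}
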