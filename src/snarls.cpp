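#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <queue>
#include <unordered_map>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Side-adjacency machinery for snarl finding. Vertices are node sides:
// v = 2*(node-1) + side, side 0 = left, 1 = right. Graph edges join side
// vertices; every node additionally has an implicit internal edge between
// its two sides, which is cut for the (at most two) nodes under test.

namespace {

struct SideGraph {
  int n;                       // nodes
  std::vector<int> head, nxt, to;  // CSR-ish adjacency over 2n side vertices
  void build(int n_nodes, const IntegerMatrix& edges) {
    n = n_nodes;
    head.assign(2 * n, -1);
    nxt.clear(); to.clear();
    for (int i = 0; i < edges.nrow(); ++i) {
      int a = 2 * (edges(i, 0) - 1) + edges(i, 1);
      int b = 2 * (edges(i, 2) - 1) + edges(i, 3);
      add(a, b); add(b, a);
    }
  }
  void add(int a, int b) {
    to.push_back(b); nxt.push_back(head[a]); head[a] = (int)to.size() - 1;
  }
};

// BFS over side vertices from `start`; nodes `cut1`/`cut2` (0-based, -1 =
// none) have their internal edge removed. Marks visited side vertices with
// `stamp` in `mark`.
void side_bfs(const SideGraph& g, int start, int cut1, int cut2,
              std::vector<int>& mark, int stamp, std::vector<int>& queue_buf) {
  queue_buf.clear();
  queue_buf.push_back(start);
  mark[start] = stamp;
  for (size_t qi = 0; qi < queue_buf.size(); ++qi) {
    int v = queue_buf[qi];
    int node = v >> 1;
    if (node != cut1 && node != cut2) {
      int w = v ^ 1;
      if (mark[w] != stamp) { mark[w] = stamp; queue_buf.push_back(w); }
    }
    for (int e = g.head[v]; e != -1; e = g.nxt[e]) {
      int w = g.to[e];
      if (mark[w] != stamp) { mark[w] = stamp; queue_buf.push_back(w); }
    }
  }
}

struct SepResult {
  bool separable;
  std::vector<int> contents;   // 0-based node indices, sorted
};

}  // namespace

// Separability of side vertices u, v (different nodes): split both nodes'
// internal edges; separable iff u and v share a component. Contents are the
// nodes of that component not reachable from either boundary's outer face.
static SepResult separable_plain(const SideGraph& g, int u, int v) {
  SepResult res; res.separable = false;
  int a = u >> 1, b = v >> 1;
  int N = 2 * g.n;
  std::vector<int> inner(N, 0), outer(N, 0), qbuf;
  int st = 0;
  ++st; side_bfs(g, u, a, b, inner, st, qbuf);
  if (inner[v] != st) return res;
  int st2 = 0;
  ++st2; side_bfs(g, u ^ 1, a, b, outer, st2, qbuf);
  side_bfs(g, v ^ 1, a, b, outer, st2, qbuf);
  res.separable = true;
  for (int nd = 0; nd < g.n; ++nd) {
    if (nd == a || nd == b) continue;
    bool inside = inner[2 * nd] == st || inner[2 * nd + 1] == st;
    bool out = outer[2 * nd] == st2 || outer[2 * nd + 1] == st2;
    if (inside && !out) res.contents.push_back(nd);
  }
  return res;
}

// [[Rcpp::export(name = ".separable_cpp")]]
List separable_cpp(int n_nodes, IntegerMatrix edges, int a_node, int a_side,
                   int b_node, int b_side) {
  SideGraph g; g.build(n_nodes, edges);
  int u = 2 * (a_node - 1) + a_side, v = 2 * (b_node - 1) + b_side;
  SepResult r = separable_plain(g, u, v);
  IntegerVector contents(r.contents.size());
  for (size_t i = 0; i < r.contents.size(); ++i) contents[i] = r.contents[i] + 1;
  return List::create(_["separable"] = r.separable, _["contents"] = contents);
}

// Full snarl finding: all separable pairs, then the minimality/chain-merge
// rule. Returns the minimal nontrivial snarls with contents and cyclic
// flags, plus the full separable pair list (for diagnostics).
// [[Rcpp::export(name = ".find_snarls_cpp")]]
List find_snarls_cpp(int n_nodes, IntegerMatrix edges) {
  SideGraph g; g.build(n_nodes, edges);
  int N = 2 * n_nodes;
  std::vector<int> qbuf;

  // Reachability pruning: R[u] = side vertices reachable from u with only
  // u's node split. (a,b) can only be separable if mutually reachable.
  std::vector<uint8_t> reach((size_t)N * N, 0);
  {
    std::vector<int> mark(N, 0); int stamp = 0;
    for (int u = 0; u < N; ++u) {
      ++stamp;
      side_bfs(g, u, u >> 1, -1, mark, stamp, qbuf);
      for (int v = 0; v < N; ++v)
        if (mark[v] == stamp) reach[(size_t)u * N + v] = 1;
    }
  }

  struct Pair { int u, v; std::vector<int> contents; };
  std::vector<Pair> pairs;
  std::unordered_map<int64_t, int> pair_idx;  // key u*N+v (u<v) -> index
  for (int u = 0; u < N; ++u) {
    for (int v = u + 1; v < N; ++v) {
      if ((u >> 1) == (v >> 1)) continue;
      if (!reach[(size_t)u * N + v] || !reach[(size_t)v * N + u]) continue;
      SepResult r = separable_plain(g, u, v);
      if (!r.separable) continue;
      pair_idx[(int64_t)u * N + v] = (int)pairs.size();
      pairs.push_back({u, v, r.contents});
    }
  }

  // endpoint index
  std::vector<std::vector<int>> by_end(N);
  for (size_t i = 0; i < pairs.size(); ++i) {
    by_end[pairs[i].u].push_back((int)i);
    by_end[pairs[i].v].push_back((int)i);
  }

  auto find_pair = [&](int x, int y) -> int {
    if (x > y) std::swap(x, y);
    auto it = pair_idx.find((int64_t)x * N + y);
    return it == pair_idx.end() ? -1 : it->second;
  };

  // scratch scope marks
  std::vector<int> in_scope(N, 0), scope_q(N, 0), scope_r(N, 0);
  int st_p = 0, st_q = 0, st_r = 0;
  std::vector<uint8_t> in_contents(n_nodes, 0);

  auto mark_scope = [&](const Pair& p, std::vector<int>& sc, int st) {
    sc[p.u] = st; sc[p.v] = st;
    for (int nd : p.contents) { sc[2 * nd] = st; sc[2 * nd + 1] = st; }
  };

  std::vector<uint8_t> removed(pairs.size(), 0);
  for (size_t pi = 0; pi < pairs.size(); ++pi) {
    Pair& p = pairs[pi];
    if (p.contents.empty()) { removed[pi] = 1; continue; }  // trivial
    for (int nd : p.contents) in_contents[nd] = 1;
    bool gone = false;
    for (int side = 0; side < 2 && !gone; ++side) {
      int endp = side == 0 ? p.u : p.v;
      int other = side == 0 ? p.v : p.u;
      for (int qi : by_end[endp]) {
        const Pair& q = pairs[qi];
        int w = (q.u == endp) ? q.v : q.u;
        int c = w >> 1;
        if (!in_contents[c]) continue;
        int ri = find_pair(w ^ 1, other);
        if (ri < 0) continue;
        const Pair& r = pairs[ri];
        if ((int)(q.contents.size() + 1 + r.contents.size()) !=
            (int)p.contents.size()) continue;
        // node cover: q.contents + {c} + r.contents == p.contents
        bool ok = true;
        for (int nd : q.contents) if (!in_contents[nd]) { ok = false; break; }
        if (ok) for (int nd : r.contents)
          if (!in_contents[nd] || nd == c) { ok = false; break; }
        if (ok) for (int nd : q.contents)
          for (int nd2 : r.contents) if (nd == nd2) { ok = false; break; }
        if (ok) for (int nd : q.contents) if (nd == c) { ok = false; break; }
        if (!ok) continue;
        // edge cover: every graph edge interior to p must be interior to q or r
        ++st_p; mark_scope(p, in_scope, st_p);
        ++st_q; mark_scope(q, scope_q, st_q);
        ++st_r; mark_scope(r, scope_r, st_r);
        bool cover = true;
        for (int i = 0; i < edges.nrow() && cover; ++i) {
          int x = 2 * (edges(i, 0) - 1) + edges(i, 1);
          int y = 2 * (edges(i, 2) - 1) + edges(i, 3);
          if (in_scope[x] == st_p && in_scope[y] == st_p) {
            bool inq = scope_q[x] == st_q && scope_q[y] == st_q;
            bool inr = scope_r[x] == st_r && scope_r[y] == st_r;
            if (!inq && !inr) cover = false;
          }
        }
        if (cover) { gone = true; break; }
      }
    }
    for (int nd : p.contents) in_contents[nd] = 0;
    if (gone) removed[pi] = 1;
  }

  // cyclicity of kept snarls: directed walk graph restricted to contents
  auto is_cyclic = [&](const Pair& p) {
    // directed vertex = side vertex meaning "about to leave via this face":
    // from face f of node nd we cross edges; arriving at face h of node m we
    // next leave via h^1 (pass through m). Restrict to contents nodes.
    std::vector<uint8_t> inc(n_nodes, 0);
    for (int nd : p.contents) inc[nd] = 1;
    std::vector<int> color(N, 0);  // 0 unvisited, 1 on stack, 2 done
    std::function<bool(int)> dfs = [&](int f) -> bool {
      color[f] = 1;
      for (int e = g.head[f]; e != -1; e = g.nxt[e]) {
        int h = g.to[e];
        if (!inc[h >> 1]) continue;
        int nf = h ^ 1;  // pass through
        if (color[nf] == 1) return true;
        if (color[nf] == 0 && dfs(nf)) return true;
      }
      color[f] = 2;
      return false;
    };
    for (int nd : p.contents)
      for (int s = 0; s < 2; ++s)
        if (color[2 * nd + s] == 0 && dfs(2 * nd + s)) return true;
    return false;
  };

  std::vector<int> keep_idx;
  for (size_t i = 0; i < pairs.size(); ++i) if (!removed[i]) keep_idx.push_back((int)i);

  IntegerMatrix snarls((int)keep_idx.size(), 4);
  List contents((int)keep_idx.size());
  LogicalVector cyclic((int)keep_idx.size());
  for (size_t i = 0; i < keep_idx.size(); ++i) {
    const Pair& p = pairs[keep_idx[i]];
    snarls(i, 0) = (p.u >> 1) + 1; snarls(i, 1) = p.u & 1;
    snarls(i, 2) = (p.v >> 1) + 1; snarls(i, 3) = p.v & 1;
    IntegerVector cv(p.contents.size());
    for (size_t j = 0; j < p.contents.size(); ++j) cv[j] = p.contents[j] + 1;
    contents[i] = cv;
    cyclic[i] = is_cyclic(p);
  }

  // all separable pairs (diagnostics / trivial adjacency info)
  IntegerMatrix all_pairs((int)pairs.size(), 5);
  for (size_t i = 0; i < pairs.size(); ++i) {
    all_pairs(i, 0) = (pairs[i].u >> 1) + 1; all_pairs(i, 1) = pairs[i].u & 1;
    all_pairs(i, 2) = (pairs[i].v >> 1) + 1; all_pairs(i, 3) = pairs[i].v & 1;
    all_pairs(i, 4) = (int)pairs[i].contents.size();
  }

  return List::create(_["snarls"] = snarls, _["contents"] = contents,
                      _["cyclic"] = cyclic, _["pairs"] = all_pairs);
}
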