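#include <Rcpp.h>
#include <vector>
#include <string>
#include <queue>
#include <map>
#include <tuple>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Base-level aligners.
//
// Scoring is match/mismatch/gap-open/gap-extend (match > 0, penalties <= 0).
// The wavefront aligner works in the equivalent penalty space
//   x = 2(M + |mismatch|), o = 2|gap_open|, e = 2|gap_extend| + M
// where minimizing penalty over a fixed-endpoint (global) alignment is
// identical to maximizing score, and score = M(|q|+|t|)/2 - penalty/2.

namespace {

const double NEG = -1e18;

struct Cigar {
  std::vector<char> op;
  std::vector<int> len;
  void push(char o, int l) {
    if (l <= 0) return;
    if (!op.empty() && op.back() == o) len.back() += l;
    else { op.push_back(o); len.push_back(l); }
  }
};

List cigar_to_list(const Cigar& c) {
  CharacterVector ops(c.op.size());
  for (size_t i = 0; i < c.op.size(); ++i) ops[i] = std::string(1, c.op[i]);
  return List::create(_["op"] = ops,
                      _["len"] = IntegerVector(c.len.begin(), c.len.end()));
}

}  // namespace

// Full-matrix global gap-affine DP (Gotoh). Score only; used as the
// independent oracle for the wavefront aligner.
// [[Rcpp::export(name = ".gotoh_score_cpp")]]
double gotoh_score_cpp(std::string q, std::string t, double match,
                       double mismatch, double gap_open, double gap_extend) {
  int n = q.size(), m = t.size();
  double oe = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> S(m + 1), E(m + 1), Sp(m + 1), Fp(m + 1), F(m + 1);
  Sp[0] = 0; Fp[0] = NEG;
  for (int j = 1; j <= m; ++j) { Sp[j] = oe + ge * (j - 1); Fp[j] = NEG; }
  std::vector<double> Ecur(m + 1, NEG);
  std::vector<double> Scur(m + 1), Fcur(m + 1);
  for (int i = 1; i <= n; ++i) {
    Scur[0] = oe + ge * (i - 1);
    Fcur[0] = Scur[0];  // running vertical gap
    Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double sub = (q[i - 1] == t[j - 1]) ? match : mismatch;
      double h = Sp[j - 1] + sub;
      Ecur[j] = std::max(Scur[j - 1] + oe, Ecur[j - 1] + ge);
      Fcur[j] = std::max(Sp[j] + oe, Fp[j] + ge);
      Scur[j] = std::max(h, std::max(Ecur[j], Fcur[j]));
    }
    std::swap(Sp, Scur); std::swap(Fp, Fcur);
  }
  return Sp[m];
}

// Gap-affine wavefront alignment (global). Returns penalty cost, a cigar
// (=/X for diagonal, I = query-consuming gap, D = target-consuming gap),
// and ok = FALSE if the cost exceeded max_cost before reaching the end.
// [[Rcpp::export(name = ".wfa_global_cpp")]]
List wfa_global_cpp(std::string q, std::string t, int x, int o, int e,
                    double max_cost) {
  int n = q.size(), m = t.size();
  // offsets are target positions h on diagonal d = h - v (v = query pos)
  int lo0 = -(n + 1), hi0 = m + 1;
  int width = hi0 - lo0 + 1;
  const int NONE = std::numeric_limits<int>::min();
  // wavefronts per score: M, I (target-consuming), D (query-consuming)
  std::vector<std::vector<int>> WM, WI, WD;
  auto get = [&](std::vector<std::vector<int>>& W, int s, int d) -> int {
    if (s < 0 || s >= (int)W.size() || W[s].empty()) return NONE;
    if (d < lo0 || d > hi0) return NONE;
    return W[s][d - lo0];
  };
  int d_end = m - n;
  int s = 0;
  WM.push_back(std::vector<int>(width, NONE));
  {
    int h = 0, v = 0;
    while (h < m && v < n && q[v] == t[h]) { ++h; ++v; }
    WM[0][0 - lo0] = h;
    if (h >= m && h - 0 == m - n + 0 && v >= n) {
      // immediate match-through
    }
  }
  auto done = [&](int s_) {
    int off = get(WM, s_, d_end);
    return off != NONE && off >= m && (off - d_end) >= n;
  };
  while (!done(s)) {
    if (s > max_cost) {
      return List::create(_["ok"] = false, _["cost"] = NA_REAL,
                          _["cigar"] = R_NilValue);
    }
    ++s;
    WM.push_back(std::vector<int>());
    WI.push_back(std::vector<int>());
    WD.push_back(std::vector<int>());
    while ((int)WI.size() <= s) WI.push_back(std::vector<int>());
    while ((int)WD.size() <= s) WD.push_back(std::vector<int>());
    while ((int)WM.size() <= s) WM.push_back(std::vector<int>());
    bool any = false;
    std::vector<int> rowM(width, NONE), rowI(width, NONE), rowD(width, NONE);
    for (int d = lo0; d <= hi0; ++d) {
      // I: gap consuming target (h+1), from d-1
      int a = get(WM, s - o - e, d - 1), b = get(WI, s - e, d - 1);
      int besti = std::max(a, b);
      if (besti != NONE) { rowI[d - lo0] = besti + 1; any = true; }
      // D: gap consuming query (v+1), offset h unchanged, from d+1
      int c = get(WM, s - o - e, d + 1), f = get(WD, s - e, d + 1);
      int bestd = std::max(c, f);
      if (bestd != NONE) { rowD[d - lo0] = bestd; any = true; }
      // M: mismatch step or close a gap
      int g = get(WM, s - x, d);
      int mm = (g == NONE) ? NONE : g + 1;
      int best = std::max(std::max(mm, rowI[d - lo0]), rowD[d - lo0]);
      if (best == NONE) continue;
      int h = best, v = h - d;
      if (v < 0 || v > n || h > m) { continue; }
      while (h < m && v < n && q[v] == t[h]) { ++h; ++v; }
      rowM[d - lo0] = h;
      any = true;
    }
    WM[s] = rowM; WI[s] = rowI; WD[s] = rowD;
    if (!any && s > (double)(x + o + e) * (n + m + 2)) break;  // safety
  }
  if (!done(s))
    return List::create(_["ok"] = false, _["cost"] = NA_REAL,
                        _["cigar"] = R_NilValue);

  // traceback
  Cigar rev;  // built back-to-front, ops appended then reversed at the end
  int d = d_end, h = m;
  char state = 'M';
  int cs = s;
  while (!(cs == 0 && state == 'M' && d == 0 && h <= 0)) {
    if (state == 'M') {
      if (cs == 0) {  // initial wavefront: pure match run back to the origin
        if (h > 0) rev.push('=', h);
        break;
      }
      int v = h - d;
      // how far did the greedy extension carry us? find entry offset
      int entry;
      int g = get(WM, cs - x, d);
      int ri = get(WI, cs, d), rd = get(WD, cs, d);
      int mm = (g == NONE) ? NONE : g + 1;
      entry = std::max(std::max(mm, ri), rd);
      int run = h - entry;
      if (run > 0) rev.push('=', run);
      h = entry; v = h - d;
      if (cs == 0 && d == 0 && h == 0) break;
      if (entry == mm && mm != NONE) { rev.push('X', 1); cs -= x; h -= 1; }
      else if (entry == ri && ri != NONE) state = 'I';
      else state = 'D';
    } else if (state == 'I') {
      // came from d-1 consuming one target char
      rev.push('D', 1);  // target-consuming: deletion from the query's view
      int a = get(WM, cs - o - e, d - 1), b = get(WI, cs - e, d - 1);
      h -= 1; d -= 1;
      if (a != NONE && a == h && !(b != NONE && b == h && false)) {
        // prefer closing the gap when both match
        cs -= o + e; state = 'M';
      } else if (b != NONE && b == h) {
        cs -= e; state = 'I';
      } else { cs -= o + e; state = 'M'; }
    } else {  // D
      rev.push('I', 1);  // query-consuming gap
      int c = get(WM, cs - o - e, d + 1), f = get(WD, cs - e, d + 1);
      d += 1;
      if (c != NONE && c == h) { cs -= o + e; state = 'M'; }
      else if (f != NONE && f == h) { cs -= e; state = 'D'; }
      else { cs -= o + e; state = 'M'; }
    }
    if (cs < 0) stop("wavefront traceback failed");
  }
  Cigar fwd;
  for (int i = (int)rev.op.size() - 1; i >= 0; --i) fwd.push(rev.op[i], rev.len[i]);
  return List::create(_["ok"] = true, _["cost"] = (double)s,
                      _["cigar"] = cigar_to_list(fwd));
}

// Pinned-start, free-end extension DP with optional X-drop. Aligns the
// query from position 0 against a prefix-region of the target. The end is
// the best-scoring cell anywhere, or, with full_query, the best cell that
// consumes the whole query (score -Inf if the X-drop envelope stopped
// short). Returns score, query/target end positions and the cigar
// (I consumes query, D consumes target).
// [[Rcpp::export(name = ".extend_dp_cpp")]]
List extend_dp_cpp(std::string q, std::string t, double match, double mismatch,
                   double gap_open, double gap_extend, double xdrop,
                   bool full_query = false) {
  int n = q.size(), m = t.size();
  double oe = gap_open + gap_extend, ge = gap_extend;
  std::vector<std::vector<double>> S(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> E = S, F = S;
  S[0][0] = 0;
  double best = 0; int bi = 0, bj = 0;
  for (int j = 1; j <= m; ++j) S[0][j] = E[0][j] = oe + ge * (j - 1);
  for (int i = 1; i <= n; ++i) {
    double rowmax = NEG;
    S[i][0] = F[i][0] = oe + ge * (i - 1);
    for (int j = 0; j <= m; ++j) {
      if (j > 0) {
        double sub = (q[i - 1] == t[j - 1]) ? match : mismatch;
        double h = S[i - 1][j - 1] + sub;
        E[i][j] = std::max(S[i][j - 1] + oe, E[i][j - 1] + ge);
        F[i][j] = std::max(S[i - 1][j] + oe, F[i - 1][j] + ge);
        S[i][j] = std::max(h, std::max(E[i][j], F[i][j]));
      }
      rowmax = std::max(rowmax, S[i][j]);
      if (S[i][j] > best) { best = S[i][j]; bi = i; bj = j; }
    }
    // X-drop: stop once the whole frontier has fallen X below the best
    if (xdrop > 0 && rowmax < best - xdrop) break;
  }
  if (full_query) {
    best = NEG; bi = n; bj = -1;
    for (int j = 0; j <= m; ++j)
      if (S[n][j] > best) { best = S[n][j]; bj = j; }
    if (bj < 0 || best <= NEG / 2)
      return List::create(_["score"] = R_NegInf, _["q_end"] = 0,
                          _["t_end"] = 0, _["cigar"] = R_NilValue);
  }
  // traceback from (bi, bj): state S (cell), E (target gap), F (query gap)
  Cigar rev;
  int i = bi, j = bj; char st = 'S';
  while (i > 0 || j > 0) {
    if (st == 'E') {
      rev.push('D', 1);
      bool opened = (E[i][j] == S[i][j - 1] + oe);
      --j;
      if (opened) st = 'S';
      continue;
    }
    if (st == 'F') {
      rev.push('I', 1);
      bool opened = (F[i][j] == S[i - 1][j] + oe);
      --i;
      if (opened) st = 'S';
      continue;
    }
    if (i == 0) { rev.push('D', j); j = 0; continue; }
    if (j == 0) { rev.push('I', i); i = 0; continue; }
    double sub = (q[i - 1] == t[j - 1]) ? match : mismatch;
    if (S[i][j] == S[i - 1][j - 1] + sub) {
      rev.push(q[i - 1] == t[j - 1] ? '=' : 'X', 1);
      --i; --j;
    } else if (S[i][j] == E[i][j]) {
      st = 'E';
    } else if (S[i][j] == F[i][j]) {
      st = 'F';
    } else {
      stop("extension traceback failed");
    }
  }
  Cigar fwd;
  for (int k = (int)rev.op.size() - 1; k >= 0; --k) fwd.push(rev.op[k], rev.len[k]);
  return List::create(_["score"] = best, _["q_end"] = bi, _["t_end"] = bj,
                      _["cigar"] = cigar_to_list(fwd));
}

// ---------------------------------------------------------------------------
// Graph alignment. The neighbourhood of the anchor is unrolled into
// "states" (node, direction, graph offset o from the origin); cycles
// re-enter at larger o, so the state graph is acyclic and states are
// processed in o order. Each state runs an affine DP over its node bases;
// entry columns merge all predecessors. Global mode requires reaching a
// fixed end position with the whole segment consumed, within a band
// |graph offset - read offset| <= band; local mode extends with an X-drop
// rule and a free end.

namespace {

struct GState {
  int node, dir, o, b0, b1;     // bases [b0, b1) consumed, traversal orient
  int col_start = -1, n_cols = 0;
  std::vector<int> preds;       // state ids feeding the entry column
  std::vector<double> entryS, entryF;
};

struct GCol {
  std::vector<double> S, E, F;
};

inline char comp_b(char c) {
  switch (c) { case 'A': return 'T'; case 'C': return 'G';
               case 'G': return 'C'; case 'T': return 'A'; default: return 'N'; }
}

std::string oriented_sub(const std::string& s, int dir) {
  if (dir == 0) return s;
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[i] = comp_b(s[s.size() - 1 - i]);
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".graph_align_cpp")]]
List graph_align_cpp(std::string read, int n_nodes, IntegerMatrix edges,
                     CharacterVector node_seqs, int start_node, int start_dir,
                     int start_off, bool has_end, int end_node, int end_dir,
                     int end_off, double match, double mismatch,
                     double gap_open, double gap_extend, double band,
                     double xdrop, int o_max) {
  int n = read.size();
  double oe = gap_open + gap_extend, ge = gap_extend;

  // face adjacency as in the distance index
  std::vector<std::vector<int>> face_adj(2 * n_nodes);
  for (int i = 0; i < edges.nrow(); ++i) {
    int an = edges(i, 0) - 1, as = edges(i, 1);
    int bn = edges(i, 2) - 1, bs = edges(i, 3);
    face_adj[2 * an + as].push_back(2 * bn + (bs == 0 ? 0 : 1));
    face_adj[2 * bn + bs].push_back(2 * an + (as == 0 ? 0 : 1));
  }
  auto exit_face = [&](int node0, int dir) {  // 0-based node
    return 2 * node0 + (dir == 0 ? 1 : 0);
  };
  auto node_len = [&](int node1) {
    return (int)LENGTH(STRING_ELT(node_seqs, node1 - 1));
  };

  std::vector<GState> states;
  std::map<std::tuple<int, int, int>, int> state_id;  // (node, dir, o)
  typedef std::pair<int, int> QE;  // (o, state id)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;

  auto get_state = [&](int node1, int dir, int o, int b0) -> int {
    auto key = std::make_tuple(node1, dir, o);
    auto it = state_id.find(key);
    if (it != state_id.end()) return it->second;
    GState st;
    st.node = node1; st.dir = dir; st.o = o; st.b0 = b0;
    st.b1 = node_len(node1);
    states.push_back(st);
    int id = (int)states.size() - 1;
    state_id[key] = id;
    pq.push({o, id});
    return id;
  };

  int s0 = get_state(start_node, start_dir, 0, start_off + 1);

  std::vector<GCol> cols;
  double best = 0; int best_state = -1, best_col = -2, best_q = 0;
  // global-mode end candidates: (state, col index or -1 for entry)
  double end_best = NEG; int end_state = -1, end_col = -2;

  std::vector<char> processed;

  while (!pq.empty()) {
    int sid = pq.top().second; pq.pop();
    if ((int)processed.size() <= sid) processed.resize(states.size(), 0);
    if (processed[sid]) continue;
    processed[sid] = 1;
    GState& st = states[sid];

    // entry arrays: origin or merge of predecessors
    st.entryS.assign(n + 1, NEG);
    st.entryF.assign(n + 1, NEG);
    if (sid == s0) {
      for (int q = 0; q <= n; ++q)
        st.entryS[q] = (q == 0) ? 0 : oe + ge * (q - 1);
    }
    for (int p : st.preds) {
      const GState& ps = states[p];
      const std::vector<double>& eS = ps.n_cols ? cols[ps.col_start + ps.n_cols - 1].S
                                                : ps.entryS;
      const std::vector<double>& eF = ps.n_cols ? cols[ps.col_start + ps.n_cols - 1].F
                                                : ps.entryF;
      for (int q = 0; q <= n; ++q) {
        if (eS[q] > st.entryS[q]) st.entryS[q] = eS[q];
        if (eF[q] > st.entryF[q]) st.entryF[q] = eF[q];
      }
    }
    if (has_end) {  // band on the entry point
      for (int q = 0; q <= n; ++q)
        if (std::fabs((double)st.o - q) > band) st.entryS[q] = st.entryF[q] = NEG;
    }
    double emax = NEG;
    for (int q = 0; q <= n; ++q) emax = std::max(emax, st.entryS[q]);
    bool dead = (emax <= NEG / 2) || (!has_end && xdrop > 0 && emax < best - xdrop);

    auto consider_end = [&](int colpos, const std::vector<double>& S) {
      if (S[n] > end_best) { end_best = S[n]; end_state = sid; end_col = colpos; }
    };
    int b0 = st.b0;
    if (has_end && st.node == end_node && st.dir == end_dir && end_off == b0)
      consider_end(-1, st.entryS);
    if (!has_end) {
      for (int q = 0; q <= n; ++q)
        if (st.entryS[q] > best) { best = st.entryS[q]; best_state = sid; best_col = -1; best_q = q; }
    }

    // process node bases
    std::string seq = oriented_sub(as<std::string>(node_seqs[st.node - 1]), st.dir);
    st.col_start = (int)cols.size();
    st.n_cols = 0;
    if (!dead) {
      const std::vector<double>* pS = &st.entryS;
      const std::vector<double>* pF = &st.entryF;
      for (int b = b0; b < st.b1; ++b) {
        GCol col; col.S.assign(n + 1, NEG); col.E.assign(n + 1, NEG);
        col.F.assign(n + 1, NEG);
        double jtot = st.o + (b - b0) + 1;
        double colmax = NEG;
        for (int q = 0; q <= n; ++q) {
          if (has_end && std::fabs(jtot - q) > band) continue;
          double Fv = std::max((*pS)[q] + oe, (*pF)[q] + ge);
          double Ev = (q > 0) ? std::max(col.S[q - 1] + oe, col.E[q - 1] + ge) : NEG;
          double Hv = NEG;
          if (q > 0 && (*pS)[q - 1] > NEG / 2) {
            double sub = (read[q - 1] == seq[b]) ? match : mismatch;
            Hv = (*pS)[q - 1] + sub;
          }
          col.F[q] = Fv; col.E[q] = Ev;
          col.S[q] = std::max(Hv, std::max(Ev, Fv));
          colmax = std::max(colmax, col.S[q]);
          if (!has_end && col.S[q] > best) {
            best = col.S[q]; best_state = sid; best_col = st.n_cols; best_q = q;
          }
        }
        cols.push_back(col);
        st.n_cols++;
        pS = &cols.back().S; pF = &cols.back().F;
        if (has_end && st.node == end_node && st.dir == end_dir &&
            end_off == b + 1)
          consider_end(st.n_cols - 1, cols.back().S);
        if (!has_end && xdrop > 0 && colmax < best - xdrop) { dead = true; break; }
      }
    }

    // successors: only when the whole node was consumed and the state is
    // still alive (dead states cannot improve anything downstream)
    bool full = (st.n_cols == st.b1 - b0);
    if (!dead && full) {
      int o2 = st.o + (st.b1 - b0);
      if (o2 <= o_max) {
        for (int f : face_adj[exit_face(st.node - 1, st.dir)]) {
          int nn = (f >> 1) + 1, nd = f & 1;
          int nid = get_state(nn, nd, o2, 0);
          states[nid].preds.push_back(sid);
        }
      }
    }
  }

  int fs, fc, fq;
  double final_score;
  if (has_end) {
    if (end_best <= NEG / 2)
      return List::create(_["ok"] = false);
    fs = end_state; fc = end_col; fq = n; final_score = end_best;
  } else {
    fs = best_state; fc = best_col; fq = best_q; final_score = best;
    if (fs < 0) {  // nothing aligned at all
      return List::create(_["ok"] = true, _["score"] = 0.0, _["q_end"] = 0,
                          _["cigar"] = cigar_to_list(Cigar()),
                          _["walk_nodes"] = IntegerVector(0),
                          _["walk_dirs"] = IntegerVector(0));
    }
  }

  // traceback
  Cigar rev;
  std::vector<int> visit;
  int cs = fs, cc = fc, q = fq;
  char stt = 'S';
  visit.push_back(cs);
  const double EPS = 1e-9;
  while (true) {
    GState& st = states[cs];
    std::string seq = oriented_sub(as<std::string>(node_seqs[st.node - 1]), st.dir);
    if (cc >= 0) {
      GCol& col = cols[st.col_start + cc];
      const std::vector<double>& pS = (cc > 0) ? cols[st.col_start + cc - 1].S : st.entryS;
      const std::vector<double>& pF = (cc > 0) ? cols[st.col_start + cc - 1].F : st.entryF;
      int b = st.b0 + cc;
      if (stt == 'S') {
        double sub = (q > 0) ? ((read[q - 1] == seq[b]) ? match : mismatch) : 0;
        if (q > 0 && std::fabs(col.S[q] - (pS[q - 1] + sub)) < EPS) {
          rev.push(read[q - 1] == seq[b] ? '=' : 'X', 1);
          --q; --cc;
        } else if (std::fabs(col.S[q] - col.E[q]) < EPS) stt = 'E';
        else if (std::fabs(col.S[q] - col.F[q]) < EPS) stt = 'F';
        else stop("graph traceback failed (S)");
      } else if (stt == 'E') {
        rev.push('I', 1);
        bool opened = std::fabs(col.E[q] - (col.S[q - 1] + oe)) < EPS;
        --q;
        if (opened) stt = 'S';
      } else {  // F: graph base consumed
        rev.push('D', 1);
        bool opened = std::fabs(col.F[q] - (pS[q] + oe)) < EPS;
        --cc;
        if (opened) stt = 'S';
      }
    } else {
      // entry column of state cs
      if (st.preds.empty()) {
        if (stt != 'S') stop("graph traceback failed (origin)");
        if (q > 0) rev.push('I', q);
        break;
      }
      bool moved = false;
      for (int p : st.preds) {
        GState& ps = states[p];
        const std::vector<double>& eS = ps.n_cols ? cols[ps.col_start + ps.n_cols - 1].S
                                                  : ps.entryS;
        const std::vector<double>& eF = ps.n_cols ? cols[ps.col_start + ps.n_cols - 1].F
                                                  : ps.entryF;
        if (stt == 'F') {
          if (std::fabs(st.entryF[q] - eF[q]) < EPS ||
              std::fabs(st.entryF[q] - (eS[q] + oe)) < EPS) {
            // gap may have opened exactly at the boundary
            bool opened = std::fabs(st.entryF[q] - (eS[q] + oe)) < EPS &&
                          !(std::fabs(st.entryF[q] - eF[q]) < EPS);
            cs = p; cc = ps.n_cols - 1; visit.push_back(cs);
            if (opened) stt = 'S';
            // the boundary itself consumes no base; continue in pred
            moved = true; break;
          }
        } else {
          if (std::fabs(st.entryS[q] - eS[q]) < EPS) {
            cs = p; cc = ps.n_cols - 1; visit.push_back(cs);
            stt = 'S'; moved = true; break;
          }
        }
      }
      if (!moved) stop("graph traceback failed (entry)");
      continue;
    }
  }

  std::vector<int> wn, wd;
  for (int i = (int)visit.size() - 1; i >= 0; --i) {
    wn.push_back(states[visit[i]].node);
    wd.push_back(states[visit[i]].dir);
  }
  Cigar fwd;
  for (int i = (int)rev.op.size() - 1; i >= 0; --i) fwd.push(rev.op[i], rev.len[i]);
  List out = List::create(_["ok"] = true, _["score"] = final_score,
                          _["cigar"] = cigar_to_list(fwd),
                          _["walk_nodes"] = IntegerVector(wn.begin(), wn.end()),
                          _["walk_dirs"] = IntegerVector(wd.begin(), wd.end()));
  if (!has_end) {
    out["q_end"] = fq;
  }
  return out;
}
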