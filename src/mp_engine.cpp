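// Maximum-parsimony engine: unordered (Fitch) state-set optimization over
// bitmask-coded characters, random-addition starting trees, TBR branch
// swapping (optionally constrained to avoid a forbidden bipartition),
// exact branch-and-bound, and bounded enumeration for small taxon sets.
//
// Node layout for unrooted binary trees on n taxa: leaves 0..n-1,
// internal nodes n..2n-3.  Character state sets are uint8 bitmasks
// (bits 0..4; bit 4 reserved for gap-as-new-state coding).

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <algorithm>
#include <vector>
#include <array>
#include <deque>
#include <set>
#include <string>

using namespace Rcpp;

static const int NONE = -1;

struct UTree {
  int n;                                  // number of taxa
  std::vector<std::array<int, 3>> nb;     // neighbor slots, NONE-padded

  explicit UTree(int n_) : n(n_), nb(2 * n_ - 2, {NONE, NONE, NONE}) {}

  int nn() const { return 2 * n - 2; }

  void link(int u, int v) {
    add_half(u, v);
    add_half(v, u);
  }
  void unlink(int u, int v) {
    del_half(u, v);
    del_half(v, u);
  }
  void add_half(int u, int v) {
    for (int k = 0; k < 3; ++k)
      if (nb[u][k] == NONE) { nb[u][k] = v; return; }
    stop("internal error: node degree exceeds 3");
  }
  void del_half(int u, int v) {
    for (int k = 0; k < 3; ++k)
      if (nb[u][k] == v) { nb[u][k] = NONE; return; }
    stop("internal error: missing half-edge");
  }
  int degree(int u) const {
    int d = 0;
    for (int k = 0; k < 3; ++k) d += (nb[u][k] != NONE);
    return d;
  }
};

// ---- conversions between ape edge matrices and UTree ----------------------

static UTree tree_from_edges(const IntegerMatrix& edge, int ntaxa) {
  int nn = 2 * ntaxa - 2;
  UTree t(ntaxa);
  if (edge.nrow() != 2 * ntaxa - 3)
    stop("tree is not an unrooted binary tree on %d taxa", ntaxa);
  for (int i = 0; i < edge.nrow(); ++i) {
    int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
    if (p < ntaxa || p >= nn || c < 0 || c >= nn)
      stop("invalid edge matrix");
    t.link(p, c);
  }
  for (int v = 0; v < ntaxa; ++v)
    if (t.degree(v) != 1) stop("leaf %d does not have degree 1", v + 1);
  for (int v = ntaxa; v < nn; ++v)
    if (t.degree(v) != 3) stop("internal node %d does not have degree 3", v + 1);
  return t;
}

// Emit ape-style edge matrix; root at the internal neighbor of leaf 0 so the
// result is a standard unrooted phylo with a basal trichotomy.
static IntegerMatrix tree_to_edges(const UTree& t) {
  int n = t.n, nn = t.nn();
  std::vector<int> newid(nn, NONE);
  for (int v = 0; v < n; ++v) newid[v] = v + 1;  // tips keep 1..n
  int root = t.nb[0][0];
  // preorder DFS assigning internal ids n+1, n+2, ...
  std::vector<std::pair<int, int>> stack;  // (node, parent)
  std::vector<std::pair<int, int>> rows;
  int next_internal = n + 1;
  stack.push_back({root, NONE});
  while (!stack.empty()) {
    auto pr = stack.back();
    stack.pop_back();
    int v = pr.first, p = pr.second;
    if (v >= n) newid[v] = next_internal++;
    if (p != NONE) rows.push_back({newid[p], v});
    // push children in reverse slot order for stable output
    for (int k = 2; k >= 0; --k) {
      int w = t.nb[v][k];
      if (w != NONE && w != p) stack.push_back({w, v});
    }
  }
  IntegerMatrix edge((int)rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    int p = rows[i].first, c = rows[i].second;
    edge(i, 0) = p;
    edge(i, 1) = (c < n) ? c + 1 : newid[c];
  }
  return edge;
}

// ---- Fitch machinery on a UTree -------------------------------------------

struct Engine {
  int n, nc;
  std::vector<uint8_t> leaf;  // n * nc leaf masks
  UTree t;
  std::mt19937 rng;

  // scratch for rooted traversals
  std::vector<int> par, order;
  std::vector<uint8_t> dn, up;
  int trav_root = NONE, trav_block = NONE;

  // true child test robust to par[] values left over from earlier
  // traversals of other components
  bool is_child(int w, int v) const {
    return w != NONE && w != par[v] && par[w] == v &&
           !(v == trav_root && w == trav_block);
  }

  Engine(int n_, int nc_, const IntegerMatrix& states, uint32_t seed)
      : n(n_), nc(nc_), leaf((size_t)n_ * nc_), t(n_), rng(seed) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < nc; ++c) {
        int m = states(i, c);
        if (m <= 0 || m > 31) stop("state mask out of range");
        leaf[(size_t)i * nc + c] = (uint8_t)m;
      }
    par.resize(t.nn());
    order.resize(t.nn());
    dn.resize((size_t)t.nn() * nc);
    up.resize((size_t)t.nn() * nc);
  }

  // preorder traversal of the component containing `root`, not crossing the
  // edge (root, block).  Returns number of nodes visited.
  int traverse(int root, int block) {
    trav_root = root;
    trav_block = block;
    int m = 0;
    order[m++] = root;
    par[root] = NONE;
    size_t head = 0;
    while (head < (size_t)m) {
      int v = order[head++];
      for (int k = 0; k < 3; ++k) {
        int w = t.nb[v][k];
        if (w == NONE || w == par[v]) continue;
        if (v == root && w == block) continue;
        par[w] = v;
        order[m++] = w;
      }
    }
    return m;
  }

  // Fitch down-pass over a traversal of length m; fills dn, returns steps.
  int down_pass(int m) {
    int steps = 0;
    for (int i = m - 1; i >= 0; --i) {
      int v = order[i];
      uint8_t* dv = &dn[(size_t)v * nc];
      if (v < n) {
        std::copy(&leaf[(size_t)v * nc], &leaf[(size_t)v * nc] + nc, dv);
        continue;
      }
      int ch[3], ncch = 0;
      for (int k = 0; k < 3; ++k) {
        int w = t.nb[v][k];
        if (is_child(w, v)) ch[ncch++] = w;
      }
      if (ncch == 1) {  // degree-2 root (should not occur on components)
        std::copy(&dn[(size_t)ch[0] * nc], &dn[(size_t)ch[0] * nc] + nc, dv);
        continue;
      }
      const uint8_t* a = &dn[(size_t)ch[0] * nc];
      const uint8_t* b = &dn[(size_t)ch[1] * nc];
      if (ncch == 2) {
        for (int c = 0; c < nc; ++c) {
          uint8_t x = a[c] & b[c];
          if (x) dv[c] = x;
          else { dv[c] = a[c] | b[c]; ++steps; }
        }
      } else {  // ncch == 3: full unrooted tree rooted at an internal node
        const uint8_t* e = &dn[(size_t)ch[2] * nc];
        for (int c = 0; c < nc; ++c) {
          uint8_t x = a[c] & b[c];
          uint8_t y;
          if (x) y = x; else { y = a[c] | b[c]; ++steps; }
          uint8_t z = y & e[c];
          if (z) dv[c] = z;
          else { dv[c] = y | e[c]; ++steps; }
        }
      }
    }
    return steps;
  }

  // Whole-tree length.  Roots at the internal neighbor of leaf 0 and folds
  // leaf 0 in at the end.  (Pairwise Fitch at a trichotomy is exact for the
  // unrooted length because the trichotomy is leaf 0's attachment node.)
  int score_full() {
    int root = t.nb[0][0];
    int m = traverse(root, 0);
    int steps = down_pass(m);
    const uint8_t* r = &dn[(size_t)root * nc];
    const uint8_t* l0 = &leaf[0];
    for (int c = 0; c < nc; ++c)
      if (!(r[c] & l0[c])) ++steps;
    return steps;
  }

  // up-pass over a traversal; up[v] = state set of the component minus the
  // subtree of v, as seen across the edge (par[v], v).  Requires the root of
  // the traversal to have exactly two children within the component.
  void up_pass(int m, int root) {
    int r1 = NONE, r2 = NONE;
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[root][k];
      if (is_child(w, root)) { (r1 == NONE ? r1 : r2) = w; }
    }
    if (r2 == NONE) stop("internal error: component root is not binary");
    std::copy(&dn[(size_t)r2 * nc], &dn[(size_t)r2 * nc] + nc,
              &up[(size_t)r1 * nc]);
    std::copy(&dn[(size_t)r1 * nc], &dn[(size_t)r1 * nc] + nc,
              &up[(size_t)r2 * nc]);
    for (int i = 0; i < m; ++i) {
      int v = order[i];
      if (v == root || v < n) continue;
      int c1 = NONE, c2 = NONE;
      for (int k = 0; k < 3; ++k) {
        int w = t.nb[v][k];
        if (is_child(w, v)) { (c1 == NONE ? c1 : c2) = w; }
      }
      if (c1 == NONE) continue;
      const uint8_t* uv = &up[(size_t)v * nc];
      uint8_t* u1 = &up[(size_t)c1 * nc];
      const uint8_t* d2 = &dn[(size_t)c2 * nc];
      uint8_t* u2 = &up[(size_t)c2 * nc];
      const uint8_t* d1 = &dn[(size_t)c1 * nc];
      for (int c = 0; c < nc; ++c) {
        uint8_t x = uv[c] & d2[c];
        u1[c] = x ? x : (uint8_t)(uv[c] | d2[c]);
        uint8_t y = uv[c] & d1[c];
        u2[c] = y ? y : (uint8_t)(uv[c] | d1[c]);
      }
    }
  }

  bool contains_clade(const std::vector<uint8_t>& inF, int sizeF) {
    int root = t.nb[0][0];
    int m = traverse(root, 0);
    std::vector<int> cnt(t.nn(), 0), sz(t.nn(), 0);
    bool found = false;
    for (int i = m - 1; i >= 0; --i) {
      int v = order[i];
      if (v < n) { cnt[v] = inF[v]; sz[v] = 1; }
      for (int k = 0; k < 3; ++k) {
        int w = t.nb[v][k];
        if (is_child(w, v)) { cnt[v] += cnt[w]; sz[v] += sz[w]; }
      }
      if (v != root) {
        if ((cnt[v] == sizeF && sz[v] == sizeF) ||
            (cnt[v] == 0 && sz[v] == n - sizeF))
          found = true;
      }
    }
    // account for leaf 0's trivial side only if F is non-trivial: a clade of
    // size 1 or n-1 is always present; callers pass non-trivial clades.
    return found;
  }

  // canonical unrooted-topology fingerprint: the sorted set of descendant
  // leaf bitsets below each internal node when rooted next to leaf 0
  // (every such set excludes leaf 0, so the representation is canonical)
  std::string tree_hash() {
    int words = (n + 63) / 64;
    int root = t.nb[0][0];
    int m = traverse(root, 0);
    std::vector<uint64_t> bits((size_t)t.nn() * words, 0);
    std::vector<std::string> splits;
    for (int i = m - 1; i >= 0; --i) {
      int v = order[i];
      uint64_t* bv = &bits[(size_t)v * words];
      if (v < n) bv[v / 64] |= (uint64_t)1 << (v % 64);
      for (int k = 0; k < 3; ++k) {
        int w = t.nb[v][k];
        if (is_child(w, v))
          for (int q = 0; q < words; ++q) bv[q] |= bits[(size_t)w * words + q];
      }
      if (v >= n && v != root)
        splits.push_back(std::string((char*)bv, words * 8));
    }
    std::sort(splits.begin(), splits.end());
    std::string out;
    for (auto& s : splits) out += s;
    return out;
  }
};

// ---- TBR sweep -------------------------------------------------------------

struct Move {
  int ea, eb;       // bisected edge endpoints (a keeps side A)
  int f1p, f1v;     // reattachment edge in A, or (NONE, NONE) = stay
  int f2p, f2v;     // reattachment edge in B, or (NONE, NONE) = stay
  int total;
};

struct Undo {
  int a, b;
  int a_c1, a_c2, f1p, f1v;  // a was detached from c1,c2 and spliced into f1
  int b_c1, b_c2, f2p, f2v;
  bool moved_a, moved_b;
};

static void apply_side(UTree& t, int node, int c1, int c2, int fp, int fv) {
  // detach `node` from between c1,c2 and splice into edge (fp,fv)
  t.unlink(node, c1);
  t.unlink(node, c2);
  t.link(c1, c2);
  t.unlink(fp, fv);
  t.link(fp, node);
  t.link(node, fv);
}

static void revert_side(UTree& t, int node, int c1, int c2, int fp, int fv) {
  t.unlink(fp, node);
  t.unlink(node, fv);
  t.link(fp, fv);
  t.unlink(c1, c2);
  t.link(node, c1);
  t.link(node, c2);
}

static Undo apply_move(UTree& t, const Move& mv) {
  Undo u;
  u.a = mv.ea; u.b = mv.eb;
  u.moved_a = (mv.f1p != NONE);
  u.moved_b = (mv.f2p != NONE);
  if (u.moved_a) {
    int c1 = NONE, c2 = NONE;
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[mv.ea][k];
      if (w != NONE && w != mv.eb) { (c1 == NONE ? c1 : c2) = w; }
    }
    u.a_c1 = c1; u.a_c2 = c2; u.f1p = mv.f1p; u.f1v = mv.f1v;
    apply_side(t, mv.ea, c1, c2, mv.f1p, mv.f1v);
  }
  if (u.moved_b) {
    int c1 = NONE, c2 = NONE;
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[mv.eb][k];
      if (w != NONE && w != mv.ea) { (c1 == NONE ? c1 : c2) = w; }
    }
    u.b_c1 = c1; u.b_c2 = c2; u.f2p = mv.f2p; u.f2v = mv.f2v;
    apply_side(t, mv.eb, c1, c2, mv.f2p, mv.f2v);
  }
  return u;
}

static void revert_move(UTree& t, const Undo& u) {
  if (u.moved_b) revert_side(t, u.b, u.b_c1, u.b_c2, u.f2p, u.f2v);
  if (u.moved_a) revert_side(t, u.a, u.a_c1, u.a_c2, u.f1p, u.f1v);
}

// Candidate reattachment views for the component obtained by cutting edge
// (a, b) on a's side.  Each view is an edge (p, v) with p,v != a, or the
// "stay" view (NONE, NONE) whose state set is dn[a].
struct SideViews {
  std::vector<int> vp, vv;          // edge endpoints (NONE,NONE = stay)
  std::vector<int> depth;           // edge depth below the component root
  std::vector<const uint8_t*> set;  // per-view state sets (nc bytes)
  std::vector<uint8_t> own;         // backing store for combined sets
  int steps;                        // unrooted length of the component
  bool single_leaf;
};

static void side_views(Engine& E, int a, int b, SideViews& sv) {
  int nc = E.nc;
  sv.vp.clear(); sv.vv.clear(); sv.set.clear(); sv.depth.clear();
  if (a < E.n) {  // single-leaf component
    sv.single_leaf = true;
    sv.steps = 0;
    sv.vp.push_back(NONE); sv.vv.push_back(NONE); sv.depth.push_back(0);
    sv.set.push_back(&E.leaf[(size_t)a * nc]);
    return;
  }
  sv.single_leaf = false;
  int m = E.traverse(a, b);
  sv.steps = E.down_pass(m);
  E.up_pass(m, a);
  // identify a's two children to avoid enumerating the merged edge twice
  int r1 = NONE, r2 = NONE;
  for (int k = 0; k < 3; ++k) {
    int w = E.t.nb[a][k];
    if (E.is_child(w, a)) { (r1 == NONE ? r1 : r2) = w; }
  }
  // "stay" view: state set = dn[a]
  sv.vp.push_back(NONE); sv.vv.push_back(NONE); sv.depth.push_back(0);
  sv.set.push_back(&E.dn[(size_t)a * nc]);
  sv.own.assign((size_t)m * nc, 0);
  size_t oi = 0;
  for (int i = 0; i < m; ++i) {
    int v = E.order[i];
    if (v == a || v == r1 || v == r2) continue;  // r1/r2 edges == merged edge
    uint8_t* dst = &sv.own[oi * nc];
    const uint8_t* d = &E.dn[(size_t)v * nc];
    const uint8_t* u = &E.up[(size_t)v * nc];
    for (int c = 0; c < nc; ++c) {
      uint8_t x = d[c] & u[c];
      dst[c] = x ? x : (uint8_t)(d[c] | u[c]);
    }
    int dep = 0;
    for (int w = v; E.par[w] != NONE; w = E.par[w]) ++dep;
    sv.vp.push_back(E.par[v]); sv.vv.push_back(v); sv.depth.push_back(dep);
    sv.set.push_back(dst);
    ++oi;
  }
}

static int join_extra(const uint8_t* A, const uint8_t* B, int nc) {
  int s = 0;
  for (int c = 0; c < nc; ++c)
    if (!(A[c] & B[c])) ++s;
  return s;
}

// One full TBR sweep.  Returns true (and applies a move) if an improving
// (or, with `forbid`, improving-and-allowed) move was found.
// mode: 0 = nearest-neighbor (regraft adjacent to the original spot),
// 1 = SPR (one side stays), 2 = full TBR.
static bool tbr_sweep(Engine& E, int& curLen, const std::vector<uint8_t>& inF,
                      int sizeF, long long* examined, int mode) {
  UTree& t = E.t;
  int nn = t.nn();
  SideViews A, B;
  std::vector<std::pair<int, int>> edges;
  for (int v = 0; v < nn; ++v)
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[v][k];
      if (w != NONE && v < w) edges.push_back({v, w});
    }
  bool constrained = sizeF > 0;
  for (auto& e : edges) {
    int a = e.first, b = e.second;
    if (a < E.n && b >= E.n) std::swap(a, b);  // keep single-leaf side on B
    side_views(E, a, b, A);
    side_views(E, b, a, B);
    int base = A.steps + B.steps;
    if (base >= curLen) continue;  // every join adds >= 0 steps
    std::vector<Move> cand;
    Move best;
    best.total = curLen;
    for (size_t i = 0; i < A.set.size(); ++i) {
      for (size_t j = 0; j < B.set.size(); ++j) {
        if (A.vp[i] == NONE && B.vp[j] == NONE) continue;  // identity
        if (mode <= 1 && A.vp[i] != NONE && B.vp[j] != NONE) continue;
        if (mode == 0 && A.depth[i] > 2 && B.depth[j] > 2) continue;
        int tot = base + join_extra(A.set[i], B.set[j], E.nc);
        if (examined) ++(*examined);
        if (tot < best.total) {
          Move mv{a, b, A.vp[i], A.vv[i], B.vp[j], B.vv[j], tot};
          if (constrained) cand.push_back(mv);
          else { best = mv; }
        }
      }
    }
    if (!constrained) {
      if (best.total < curLen) {
        apply_move(t, best);
        curLen = best.total;
        return true;
      }
    } else if (!cand.empty()) {
      std::sort(cand.begin(), cand.end(),
                [](const Move& x, const Move& y) { return x.total < y.total; });
      for (auto& mv : cand) {
        Undo u = apply_move(t, mv);
        if (E.contains_clade(inF, sizeF)) {
          revert_move(t, u);
        } else {
          curLen = mv.total;
          return true;
        }
      }
    }
  }
  return false;
}

// Collect all moves (respecting `mode`) whose resulting length equals
// `target`, up to `cap`.
static void collect_moves(Engine& E, int target, int mode,
                          std::vector<Move>& out, size_t cap) {
  UTree& t = E.t;
  SideViews A, B;
  std::vector<std::pair<int, int>> edges;
  for (int v = 0; v < t.nn(); ++v)
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[v][k];
      if (w != NONE && v < w) edges.push_back({v, w});
    }
  for (auto& e : edges) {
    if (out.size() >= cap) return;
    int a = e.first, b = e.second;
    if (a < E.n && b >= E.n) std::swap(a, b);
    side_views(E, a, b, A);
    side_views(E, b, a, B);
    int base = A.steps + B.steps;
    if (base > target) continue;
    for (size_t i = 0; i < A.set.size() && out.size() < cap; ++i)
      for (size_t j = 0; j < B.set.size() && out.size() < cap; ++j) {
        if (A.vp[i] == NONE && B.vp[j] == NONE) continue;
        if (mode <= 1 && A.vp[i] != NONE && B.vp[j] != NONE) continue;
        if (mode == 0 && A.depth[i] > 2 && B.depth[j] > 2) continue;
        int tot = base + join_extra(A.set[i], B.set[j], E.nc);
        if (tot == target)
          out.push_back({a, b, A.vp[i], A.vv[i], B.vp[j], B.vv[j], tot});
      }
  }
}

// ---- exported: scoring ------------------------------------------------------

// Generalized (Sankoff, unit-cost) parsimony length of an arbitrary rooted or
// unrooted tree, exact for polytomies and ambiguous cells.  Returns total and
// per-character steps.
// [[Rcpp::export]]
List cpp_score_sankoff(IntegerMatrix edge, int ntaxa, IntegerMatrix states,
                       int nstates) {
  int nc = states.ncol();
  int nnode = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    nnode = std::max(nnode, std::max(edge(i, 0), edge(i, 1)));
  std::vector<std::vector<int>> kids(nnode + 1);
  std::vector<bool> haspar(nnode + 1, false);
  for (int i = 0; i < edge.nrow(); ++i) {
    kids[edge(i, 0)].push_back(edge(i, 1));
    haspar[edge(i, 1)] = true;
  }
  int root = NONE;
  for (int v = ntaxa + 1; v <= nnode; ++v)
    if (!haspar[v] && !kids[v].empty()) root = v;
  if (root == NONE) stop("could not find tree root");
  // postorder
  std::vector<int> order, stack{root};
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (int w : kids[v]) stack.push_back(w);
  }
  const int INF = 1 << 28;
  IntegerVector per(nc);
  long long total = 0;
  std::vector<int> cost((size_t)(nnode + 1) * nstates);
  for (int c = 0; c < nc; ++c) {
    for (auto it = order.rbegin(); it != order.rend(); ++it) {
      int v = *it;
      int* cv = &cost[(size_t)v * nstates];
      if (v <= ntaxa) {
        int m = states(v - 1, c);
        for (int s = 0; s < nstates; ++s)
          cv[s] = (m >> s & 1) ? 0 : INF;
        continue;
      }
      for (int s = 0; s < nstates; ++s) cv[s] = 0;
      for (int w : kids[v]) {
        int* cw = &cost[(size_t)w * nstates];
        int mn = INF;
        for (int s = 0; s < nstates; ++s) mn = std::min(mn, cw[s]);
        for (int s = 0; s < nstates; ++s)
          cv[s] += std::min(cw[s], mn + 1);
      }
    }
    int best = INF;
    int* cr = &cost[(size_t)root * nstates];
    for (int s = 0; s < nstates; ++s) best = std::min(best, cr[s]);
    per[c] = best;
    total += best;
  }
  return List::create(_["total"] = (double)total, _["per_char"] = per);
}

// Bit-set Fitch length of an unrooted binary tree (the search engine's
// scoring path).  Total steps only.
// [[Rcpp::export]]
int cpp_fitch_bitset(IntegerMatrix edge, int ntaxa, IntegerMatrix states) {
  Engine E(ntaxa, states.ncol(), states, 1u);
  E.t = tree_from_edges(edge, ntaxa);
  return E.score_full();
}

// ---- exported: stepwise addition -------------------------------------------

// [[Rcpp::export]]
List cpp_stepwise(IntegerMatrix states, IntegerVector order0, int seed) {
  int n = states.nrow(), nc = states.ncol();
  if (n < 3) stop("need at least 3 taxa");
  Engine E(n, nc, states, (uint32_t)seed);
  std::vector<int> ord(order0.begin(), order0.end());  // 0-based taxon order
  UTree& t = E.t;
  int hub = n;  // first internal node joins the first three taxa
  t.link(hub, ord[0]);
  t.link(hub, ord[1]);
  t.link(hub, ord[2]);
  int next_internal = n + 1;
  for (int k = 3; k < n; ++k) {
    int x = ord[k];
    // root the current tree at leaf ord[0]; views for every edge (par, v)
    int m = E.traverse(ord[0], NONE);
    E.down_pass(m);
    // up sets with a leaf root: child of root gets the root's leaf set
    int rc = NONE;
    for (int q = 0; q < 3; ++q)
      if (t.nb[ord[0]][q] != NONE) rc = t.nb[ord[0]][q];
    std::copy(&E.leaf[(size_t)ord[0] * nc], &E.leaf[(size_t)ord[0] * nc] + nc,
              &E.up[(size_t)rc * nc]);
    for (int i = 0; i < m; ++i) {
      int v = E.order[i];
      if (v < n) continue;
      int c1 = NONE, c2 = NONE;
      for (int q = 0; q < 3; ++q) {
        int w = t.nb[v][q];
        if (E.is_child(w, v)) { (c1 == NONE ? c1 : c2) = w; }
      }
      if (c1 == NONE) continue;
      const uint8_t* uv = &E.up[(size_t)v * nc];
      const uint8_t* d1 = &E.dn[(size_t)c1 * nc];
      const uint8_t* d2 = &E.dn[(size_t)c2 * nc];
      uint8_t* u1 = &E.up[(size_t)c1 * nc];
      uint8_t* u2 = &E.up[(size_t)c2 * nc];
      for (int c = 0; c < nc; ++c) {
        uint8_t xx = uv[c] & d2[c];
        u1[c] = xx ? xx : (uint8_t)(uv[c] | d2[c]);
        uint8_t yy = uv[c] & d1[c];
        u2[c] = yy ? yy : (uint8_t)(uv[c] | d1[c]);
      }
    }
    const uint8_t* lx = &E.leaf[(size_t)x * nc];
    int bestCost = INT_MAX, nties = 0, bp = NONE, bv = NONE;
    std::vector<uint8_t> view(nc);
    for (int i = 0; i < m; ++i) {
      int v = E.order[i];
      if (v == ord[0]) continue;
      const uint8_t* d = &E.dn[(size_t)v * nc];
      const uint8_t* u = &E.up[(size_t)v * nc];
      int cost = 0;
      for (int c = 0; c < nc; ++c) {
        uint8_t xx = d[c] & u[c];
        uint8_t r = xx ? xx : (uint8_t)(d[c] | u[c]);
        if (!(r & lx[c])) ++cost;
      }
      if (cost < bestCost) {
        bestCost = cost; nties = 1; bp = E.par[v]; bv = v;
      } else if (cost == bestCost) {
        // reservoir tie-break from the seeded stream
        ++nties;
        if (std::uniform_int_distribution<int>(0, nties - 1)(E.rng) == 0) {
          bp = E.par[v]; bv = v;
        }
      }
    }
    int mnode = next_internal++;
    t.unlink(bp, bv);
    t.link(bp, mnode);
    t.link(mnode, bv);
    t.link(mnode, x);
  }
  int len = E.score_full();
  return List::create(_["edge"] = tree_to_edges(t), _["length"] = len);
}

// ---- exported: TBR search ---------------------------------------------------

// [[Rcpp::export]]
List cpp_tbr(IntegerMatrix states, IntegerMatrix edge, int seed,
             IntegerVector forbid0, int mode = 2, int plateau_cap = 150,
             int max_iter = 100000) {
  int n = states.nrow();
  Engine E(n, states.ncol(), states, (uint32_t)seed);
  E.t = tree_from_edges(edge, n);
  std::vector<uint8_t> inF(n, 0);
  int sizeF = forbid0.size();
  for (int i = 0; i < sizeF; ++i) inF[forbid0[i]] = 1;
  if (sizeF > 0) {
    // push the start tree outside the forbidden clade if necessary
    int guard = 0;
    while (E.contains_clade(inF, sizeF) && guard++ < 200) {
      std::vector<int> inside, outside;
      for (int v = 0; v < n; ++v) (inF[v] ? inside : outside).push_back(v);
      int x = inside[std::uniform_int_distribution<int>(
          0, (int)inside.size() - 1)(E.rng)];
      int y = outside[std::uniform_int_distribution<int>(
          0, (int)outside.size() - 1)(E.rng)];
      // SPR leaf x onto leaf y's pendant edge
      int px = E.t.nb[x][0], py = E.t.nb[y][0];
      if (px == py) continue;
      int c1 = NONE, c2 = NONE;
      for (int k = 0; k < 3; ++k) {
        int w = E.t.nb[px][k];
        if (w != NONE && w != x) { (c1 == NONE ? c1 : c2) = w; }
      }
      apply_side(E.t, px, c1, c2, py, y);
    }
    if (E.contains_clade(inF, sizeF))
      stop("could not construct a start tree avoiding the constraint");
  }
  int curLen = E.score_full();
  int startLen = curLen;
  long long examined = 0;
  int improvements = 0, iters = 0;
  while (iters++ < max_iter) {
    // steepest descent to a strict local optimum
    while (tbr_sweep(E, curLen, inF, sizeF, &examined, mode)) ++improvements;
    if (plateau_cap <= 0) break;
    // plateau hopping: breadth-first over equal-length TBR neighbors,
    // trying an improving sweep from each (PAUP-style swapping on all
    // retained equally parsimonious trees)
    std::set<std::string> seen;
    std::deque<std::vector<std::array<int, 3>>> dq;
    seen.insert(E.tree_hash());
    dq.push_back(E.t.nb);
    bool improved = false;
    int visited = 0;
    while (!dq.empty() && visited < plateau_cap) {
      E.t.nb = dq.front();
      dq.pop_front();
      ++visited;
      int len2 = curLen;
      if (tbr_sweep(E, len2, inF, sizeF, &examined, mode)) {
        curLen = len2;
        ++improvements;
        improved = true;
        break;
      }
      std::vector<Move> eq;
      collect_moves(E, curLen, mode, eq, 4000);
      for (auto& mv : eq) {
        if ((int)dq.size() >= plateau_cap) break;
        Undo u = apply_move(E.t, mv);
        bool ok = (sizeF == 0) || !E.contains_clade(inF, sizeF);
        if (ok) {
          std::string h = E.tree_hash();
          if (seen.insert(h).second) dq.push_back(E.t.nb);
        }
        revert_move(E.t, u);
      }
    }
    if (!improved) break;
  }
  return List::create(_["edge"] = tree_to_edges(E.t), _["length"] = curLen,
                      _["start_length"] = startLen,
                      _["improvements"] = improvements,
                      _["examined"] = (double)examined);
}

// All TBR neighbors of `edge` with length exactly `target`, as edge
// matrices (capped).  Used to expand the retained optimal-tree buffer.
// [[Rcpp::export]]
List cpp_equal_neighbors(IntegerMatrix states, IntegerMatrix edge, int target,
                         int cap) {
  int n = states.nrow();
  Engine E(n, states.ncol(), states, 1u);
  E.t = tree_from_edges(edge, n);
  UTree& t = E.t;
  std::vector<std::pair<int, int>> edges;
  for (int v = 0; v < t.nn(); ++v)
    for (int k = 0; k < 3; ++k) {
      int w = t.nb[v][k];
      if (w != NONE && v < w) edges.push_back({v, w});
    }
  SideViews A, B;
  std::vector<IntegerMatrix> found;
  for (auto& e : edges) {
    if ((int)found.size() >= cap) break;
    int a = e.first, b = e.second;
    if (a < E.n && b >= E.n) std::swap(a, b);
    side_views(E, a, b, A);
    side_views(E, b, a, B);
    int base = A.steps + B.steps;
    if (base > target) continue;
    for (size_t i = 0; i < A.set.size() && (int)found.size() < cap; ++i)
      for (size_t j = 0; j < B.set.size() && (int)found.size() < cap; ++j) {
        if (A.vp[i] == NONE && B.vp[j] == NONE) continue;
        int tot = base + join_extra(A.set[i], B.set[j], E.nc);
        if (tot != target) continue;
        Move mv{a, b, A.vp[i], A.vv[i], B.vp[j], B.vv[j], tot};
        Undo u = apply_move(t, mv);
        found.push_back(tree_to_edges(t));
        revert_move(t, u);
      }
  }
  List out(found.size());
  for (size_t i = 0; i < found.size(); ++i) out[i] = found[i];
  return out;
}

// ---- exported: branch and bound / enumeration ------------------------------

struct BnB {
  int n, nc;
  Engine E;
  std::vector<int> ord;
  int best;
  int slack;        // collect trees with length <= best + slack
  bool fixed_cap;   // if true, `best` is a fixed ceiling (enumeration mode)
  int maxtrees;
  std::vector<IntegerMatrix> trees;
  std::vector<int> lens;
  bool overflow = false;

  BnB(const IntegerMatrix& states, int upper, int slack_, bool fixed,
      int maxtrees_)
      : n(states.nrow()), nc(states.ncol()), E(n, nc, states, 1u),
        best(upper), slack(slack_), fixed_cap(fixed), maxtrees(maxtrees_) {
    for (int i = 0; i < n; ++i) ord.push_back(i);
  }

  void recurse(int k, int next_internal) {
    UTree& t = E.t;
    if (k == n) {
      int len = E.score_full();
      if (len > best + slack) return;
      if (!fixed_cap && len < best) {
        best = len;
        // drop now-suboptimal collected trees
        std::vector<IntegerMatrix> keep;
        std::vector<int> kl;
        for (size_t i = 0; i < lens.size(); ++i)
          if (lens[i] <= best + slack) { keep.push_back(trees[i]); kl.push_back(lens[i]); }
        trees.swap(keep); lens.swap(kl);
      }
      if ((int)trees.size() < maxtrees) {
        trees.push_back(tree_to_edges(t));
        lens.push_back(len);
      } else overflow = true;
      return;
    }
    int x = ord[k];
    // nodes not yet inserted have empty adjacency, so this scan yields
    // exactly the current tree's edges
    std::vector<std::pair<int, int>> edges;
    for (int v = 0; v < t.nn(); ++v)
      for (int q = 0; q < 3; ++q) {
        int w = t.nb[v][q];
        if (w != NONE && v < w) edges.push_back({v, w});
      }
    for (auto& e : edges) {
      int u = e.first, v = e.second;
      int mnode = next_internal;
      t.unlink(u, v);
      t.link(u, mnode); t.link(mnode, v); t.link(mnode, x);
      int len = E.score_full();
      if (len <= best + slack) recurse(k + 1, next_internal + 1);
      t.unlink(u, mnode); t.unlink(mnode, v); t.unlink(mnode, x);
      t.link(u, v);
    }
  }

  void run() {
    UTree& t = E.t;
    int hub = n;
    t.link(hub, ord[0]); t.link(hub, ord[1]); t.link(hub, ord[2]);
    recurse(3, n + 1);
  }
};

// Exact search: all optimal unrooted binary topologies.  `upper` is an
// initial upper bound on the optimum (use a heuristic result, or a large
// number).
// [[Rcpp::export]]
List cpp_branch_and_bound(IntegerMatrix states, int upper, int maxtrees) {
  BnB bb(states, upper, 0, false, maxtrees);
  bb.run();
  // keep only trees at exactly the final optimum
  List out;
  for (size_t i = 0; i < bb.lens.size(); ++i)
    if (bb.lens[i] == bb.best) out.push_back(bb.trees[i]);
  return List::create(_["best"] = bb.best, _["trees"] = out,
                      _["overflow"] = bb.overflow);
}

// Enumeration: every unrooted binary topology with length <= ceiling.
// [[Rcpp::export]]
List cpp_enumerate_le(IntegerMatrix states, int ceiling, int maxtrees) {
  BnB bb(states, ceiling, 0, true, maxtrees);
  bb.run();
  IntegerVector lens(bb.lens.begin(), bb.lens.end());
  List trees;
  for (auto& tr : bb.trees) trees.push_back(tr);
  return List::create(_["lengths"] = lens, _["trees"] = trees,
                      _["overflow"] = bb.overflow);
}
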