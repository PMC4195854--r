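// Shared kernels: clock-tree structures, JC69 pruning with per-pattern
// scaling, and the multispecies-coalescent log density. All node indices are
// 0-based; tips come first (0..ntip-1).
#ifndef COALDELIM_CTREE_H
#define COALDELIM_CTREE_H

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

static const double CD_NEG_INF = -std::numeric_limits<double>::infinity();
static const double CD_LIFT = 1e256;
static const double CD_LOG_LIFT = std::log(1e256);

struct GTree {
  int ntip, nnode, root;               // nnode = 2*ntip - 1
  std::vector<int> par, ch1, ch2;      // -1 where absent; tips have no children
  std::vector<double> age;             // tips at 0
  std::vector<int> pop;                // per tip: index of its population

  void init(int ntip_) {
    ntip = ntip_; nnode = 2 * ntip - 1;
    par.assign(nnode, -1); ch1.assign(nnode, -1); ch2.assign(nnode, -1);
    age.assign(nnode, 0.0); pop.assign(ntip, 0);
  }
  void rebuild_children() {
    std::fill(ch1.begin(), ch1.end(), -1);
    std::fill(ch2.begin(), ch2.end(), -1);
    root = -1;
    for (int v = 0; v < nnode; ++v) {
      int p = par[v];
      if (p < 0) { root = v; continue; }
      if (ch1[p] < 0) ch1[p] = v; else ch2[p] = v;
    }
  }
  // postorder list of internal nodes (children before parents)
  void postorder_internal(std::vector<int> &out) const {
    out.clear();
    static thread_local std::vector<int> stack, order;
    stack.clear(); order.clear();
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      if (ch1[v] >= 0) { stack.push_back(ch1[v]); stack.push_back(ch2[v]); }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i)
      if (order[i] >= ntip) out.push_back(order[i]);
  }
  bool is_ancestor(int a, int b) const {  // is a an ancestor of b?
    int v = par[b];
    while (v >= 0) { if (v == a) return true; v = par[v]; }
    return false;
  }
};

// ---- sequence data, compressed site patterns ----

struct PatternData {
  int ntip, npat;
  std::vector<int> st;        // st[tip*npat + p] in 0..3
  std::vector<double> w;      // pattern multiplicities
};

// ---- JC69 pruning with cached partials ----

struct Partials {
  int ntip, npat, nint;
  std::vector<double> L;      // [(vi*npat + p)*4 + x], vi = v - ntip
  std::vector<int> scl;       // per internal node, per pattern lift count

  void init(int ntip_, int npat_) {
    ntip = ntip_; npat = npat_; nint = ntip - 1;
    L.assign((size_t)nint * npat * 4, 0.0);
    scl.assign((size_t)nint * npat, 0);
  }
  double *block(int v) { return &L[((size_t)(v - ntip) * npat) * 4]; }
  int *sblock(int v) { return &scl[(size_t)(v - ntip) * npat]; }
};

inline void cd_comp_node(const GTree &g, const PatternData &pd, Partials &P,
                         int v) {
  const int npat = pd.npat;
  double *out = P.block(v);
  int *so = P.sblock(v);
  const int ch[2] = {g.ch1[v], g.ch2[v]};
  // first child initialises, second multiplies in
  for (int k = 0; k < 2; ++k) {
    int c = ch[k];
    double t = g.age[v] - g.age[c];
    double E = std::exp(-4.0 / 3.0 * t);
    double pdif = 0.25 * (1.0 - E);
    if (c < g.ntip) {
      const int *s = &pd.st[(size_t)c * npat];
      if (k == 0) {
        for (int p = 0; p < npat; ++p) {
          double *o = out + 4 * p;
          o[0] = o[1] = o[2] = o[3] = pdif;
          o[s[p]] += E;
          so[p] = 0;
        }
      } else {
        for (int p = 0; p < npat; ++p) {
          double *o = out + 4 * p;
          int sp = s[p];
          o[0] *= pdif + (sp == 0 ? E : 0.0);
          o[1] *= pdif + (sp == 1 ? E : 0.0);
          o[2] *= pdif + (sp == 2 ? E : 0.0);
          o[3] *= pdif + (sp == 3 ? E : 0.0);
        }
      }
    } else {
      const double *Lc = P.block(c);
      const int *sc = P.sblock(c);
      if (k == 0) {
        for (int p = 0; p < npat; ++p) {
          const double *l = Lc + 4 * p;
          double S = l[0] + l[1] + l[2] + l[3];
          double base = pdif * S;
          double *o = out + 4 * p;
          o[0] = base + E * l[0]; o[1] = base + E * l[1];
          o[2] = base + E * l[2]; o[3] = base + E * l[3];
          so[p] = sc[p];
        }
      } else {
        for (int p = 0; p < npat; ++p) {
          const double *l = Lc + 4 * p;
          double S = l[0] + l[1] + l[2] + l[3];
          double base = pdif * S;
          double *o = out + 4 * p;
          o[0] *= base + E * l[0]; o[1] *= base + E * l[1];
          o[2] *= base + E * l[2]; o[3] *= base + E * l[3];
          so[p] += sc[p];
        }
      }
    }
  }
  // rescale patterns that have drifted toward underflow
  for (int p = 0; p < npat; ++p) {
    double *o = out + 4 * p;
    double m = std::max(std::max(o[0], o[1]), std::max(o[2], o[3]));
    if (m < 1.0 / CD_LIFT && m > 0.0) {
      o[0] *= CD_LIFT; o[1] *= CD_LIFT; o[2] *= CD_LIFT; o[3] *= CD_LIFT;
      so[p] += 1;
    }
  }
}

inline double cd_root_loglik(const GTree &g, const PatternData &pd,
                             Partials &P) {
  const int npat = pd.npat;
  const double *Lr = P.block(g.root);
  const int *sr = P.sblock(g.root);
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    const double *l = Lr + 4 * p;
    double s = l[0] + l[1] + l[2] + l[3];
    ll += pd.w[p] * (std::log(0.25 * s) - sr[p] * CD_LOG_LIFT);
  }
  return ll;
}

inline double cd_full_loglik(const GTree &g, const PatternData &pd,
                             Partials &P) {
  static thread_local std::vector<int> po;
  g.postorder_internal(po);
  for (int v : po) cd_comp_node(g, pd, P, v);
  return cd_root_loglik(g, pd, P);
}

// recompute node v (if internal) and its ancestors; returns new loglik
inline double cd_update_path(const GTree &g, const PatternData &pd,
                             Partials &P, int v) {
  if (v < g.ntip) v = g.par[v];
  while (v >= 0) { cd_comp_node(g, pd, P, v); v = g.par[v]; }
  return cd_root_loglik(g, pd, P);
}

// snapshot/restore of partials along an ancestor path (for MH rejection)
struct PathSnapshot {
  std::vector<int> nodes;
  std::vector<double> L;
  std::vector<int> scl;
  void take(const GTree &g, Partials &P, int v) {
    nodes.clear(); L.clear(); scl.clear();
    if (v < g.ntip) v = g.par[v];
    while (v >= 0) {
      nodes.push_back(v);
      double *b = P.block(v);
      L.insert(L.end(), b, b + 4 * P.npat);
      int *s = P.sblock(v);
      scl.insert(scl.end(), s, s + P.npat);
      v = g.par[v];
    }
  }
  void restore(Partials &P) {
    size_t off = 0, soff = 0;
    for (int v : nodes) {
      std::copy(L.begin() + off, L.begin() + off + 4 * P.npat, P.block(v));
      std::copy(scl.begin() + soff, scl.begin() + soff + P.npat, P.sblock(v));
      off += 4 * P.npat; soff += P.npat;
    }
  }
};

// ---- multispecies coalescent log density ----
//
// Generic over a "model tree" given as parent/child arrays with node ages tau
// (tips 0) and per-node theta (theta of the branch above the node; the root
// entry is the ancestral-most population). Gene tips map to model tips via
// GTree::pop. Returns -Inf for gene trees incompatible with the model.

struct ModelTree {
  int ntip, nnode, root;
  std::vector<int> par, ch1, ch2;
  std::vector<double> tau, theta;
  std::vector<int> depth;

  void rebuild() {
    nnode = (int)par.size();
    ch1.assign(nnode, -1); ch2.assign(nnode, -1); root = -1;
    for (int v = 0; v < nnode; ++v) {
      if (par[v] < 0) { root = v; continue; }
      if (ch1[par[v]] < 0) ch1[par[v]] = v; else ch2[par[v]] = v;
    }
    depth.assign(nnode, 0);
    // BFS from root for depths
    std::vector<int> stack; stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (ch1[v] >= 0) {
        depth[ch1[v]] = depth[v] + 1; depth[ch2[v]] = depth[v] + 1;
        stack.push_back(ch1[v]); stack.push_back(ch2[v]);
      }
    }
  }
  int mrca(int a, int b) const {
    while (a != b) {
      if (depth[a] < depth[b]) b = par[b]; else a = par[a];
    }
    return a;
  }
  void postorder(std::vector<int> &out) const {
    out.clear();
    std::vector<int> stack, order;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      if (ch1[v] >= 0) { stack.push_back(ch1[v]); stack.push_back(ch2[v]); }
    }
    out.assign(order.rbegin(), order.rend());
  }
};

// gene tip -> model tip given by tipmap (length g.ntip).
// Uses thread-local scratch buffers: the density sits on the innermost loop
// of both MCMC engines.
inline double cd_msc_logdensity(const GTree &g, const ModelTree &M,
                                const std::vector<int> &tipmap) {
  const int nn = g.nnode;
  static thread_local std::vector<int> po, stack, origin, cnt, start, nin,
      mpo;
  static thread_local std::vector<double> coal;
  // postorder of internal gene nodes
  po.clear();
  stack.clear();
  stack.push_back(g.root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    po.push_back(v);
    if (g.ch1[v] >= 0) { stack.push_back(g.ch1[v]); stack.push_back(g.ch2[v]); }
  }
  std::reverse(po.begin(), po.end());  // children before parents (with tips)
  origin.assign(nn, -1);
  cnt.assign(M.nnode, 0);
  for (int t = 0; t < g.ntip; ++t) origin[t] = tipmap[t];
  for (int v : po) {
    if (v < g.ntip) continue;
    int m = M.mrca(origin[g.ch1[v]], origin[g.ch2[v]]);
    if (g.age[v] < M.tau[m] - 1e-15) return CD_NEG_INF;
    while (M.par[m] >= 0 && M.tau[M.par[m]] <= g.age[v]) m = M.par[m];
    origin[v] = m;  // branch assignment of the coalescence
    cnt[m]++;
  }
  // bucket the coalescence ages per branch, then insertion-sort each bucket
  start.assign(M.nnode + 1, 0);
  for (int b = 0; b < M.nnode; ++b) start[b + 1] = start[b] + cnt[b];
  coal.resize(start[M.nnode]);
  {
    static thread_local std::vector<int> fill;
    fill.assign(start.begin(), start.end() - 1);
    for (int v : po)
      if (v >= g.ntip) coal[fill[origin[v]]++] = g.age[v];
  }
  for (int b = 0; b < M.nnode; ++b) {
    for (int i = start[b] + 1; i < start[b + 1]; ++i) {
      double x = coal[i];
      int j = i - 1;
      while (j >= start[b] && coal[j] > x) { coal[j + 1] = coal[j]; j--; }
      coal[j + 1] = x;
    }
  }
  nin.assign(M.nnode, 0);
  for (int t = 0; t < g.ntip; ++t) nin[tipmap[t]] += 1;
  // model-tree postorder
  mpo.clear();
  stack.clear();
  stack.push_back(M.root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    mpo.push_back(v);
    if (M.ch1[v] >= 0) { stack.push_back(M.ch1[v]); stack.push_back(M.ch2[v]); }
  }
  double logd = 0.0;
  for (int bi = (int)mpo.size() - 1; bi >= 0; --bi) {
    int b = mpo[bi];
    if (M.ch1[b] >= 0)
      nin[b] += (nin[M.ch1[b]] - cnt[M.ch1[b]]) +
                (nin[M.ch2[b]] - cnt[M.ch2[b]]);
    int j = nin[b];
    double th = M.theta[b], t0 = M.tau[b];
    double inv_th = 1.0 / th, log2th = std::log(2.0 * inv_th);
    for (int i = start[b]; i < start[b + 1]; ++i) {
      double tc = coal[i];
      logd += log2th - j * (j - 1) * (tc - t0) * inv_th;
      t0 = tc; j -= 1;
      if (j < 1 && i + 1 < start[b + 1]) return CD_NEG_INF;
    }
    if (M.par[b] >= 0 && j > 1)
      logd += -j * (j - 1) * (M.tau[M.par[b]] - t0) * inv_th;
  }
  return logd;
}

// Yule prior on a labeled history with node ages. The kernel is the pure
// birth process run from the root: every branch survives unsplit over its
// length and every non-root internal node is a birth, exp(-lambda * L) with
// L = 2*t_root + sum of non-root internal ages (the tree's total branch
// length). The lambda power is taken as n-1 (one factor per speciation
// event including the root), the variant that keeps the induced prior on
// the overall time scale balanced under f(lambda) = 1/lambda; the topology
// marginal is uniform over labeled histories either way.
inline double cd_yule_logprior(const ModelTree &M, double lambda) {
  double H = M.tau[M.root];
  for (int v = 0; v < M.nnode; ++v)
    if (M.ch1[v] >= 0) H += M.tau[v];
  return (M.ntip - 1) * std::log(lambda) - lambda * H;
}

#endif
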