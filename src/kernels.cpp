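// JC69 pruning likelihood and per-edge branch-length optimisation for
// arbitrary (rooted or unrooted-with-basal-trifurcation) trees.
#include "ctree.h"
using namespace Rcpp;

namespace {

struct ATree {
  int ntip, nnodes;
  std::vector<std::vector<int>> ch;
  std::vector<int> par, eidx;          // eidx[v]: row of edge to parent
  std::vector<double> el;
  int root;

  void build(const IntegerMatrix &edge, int ntip_, const NumericVector &el_) {
    ntip = ntip_;
    nnodes = 0;
    for (int i = 0; i < edge.nrow(); ++i)
      nnodes = std::max(nnodes, std::max(edge(i, 0), edge(i, 1)));
    ch.assign(nnodes, {});
    par.assign(nnodes, -1);
    eidx.assign(nnodes, -1);
    el.assign(el_.begin(), el_.end());
    for (int i = 0; i < edge.nrow(); ++i) {
      int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
      ch[p].push_back(c);
      par[c] = p;
      eidx[c] = i;
    }
    root = -1;
    for (int v = 0; v < nnodes; ++v) if (par[v] < 0 && !ch[v].empty()) root = v;
  }
  void postorder(std::vector<int> &out) const {
    out.clear();
    std::vector<int> stack{root}, order;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      for (int c : ch[v]) stack.push_back(c);
    }
    out.assign(order.rbegin(), order.rend());
  }
};

// contribution of child c across its parent edge, into `out` (multiplied in
// if mult). down[] are per-node 4*npat arrays.
inline void edge_contrib(const ATree &T, const PatternData &pd,
                         const std::vector<double> &down, int c, double t,
                         double *out, bool mult) {
  int npat = pd.npat;
  double E = std::exp(-4.0 / 3.0 * t);
  double pdif = 0.25 * (1.0 - E);
  const double *dc = &down[(size_t)c * 4 * npat];
  for (int p = 0; p < npat; ++p) {
    const double *l = dc + 4 * p;
    double S = l[0] + l[1] + l[2] + l[3];
    double base = pdif * S;
    double *o = out + 4 * p;
    if (mult) {
      o[0] *= base + E * l[0]; o[1] *= base + E * l[1];
      o[2] *= base + E * l[2]; o[3] *= base + E * l[3];
    } else {
      o[0] = base + E * l[0]; o[1] = base + E * l[1];
      o[2] = base + E * l[2]; o[3] = base + E * l[3];
    }
  }
}

void comp_down(const ATree &T, const PatternData &pd,
               std::vector<double> &down, std::vector<int> &scl, int v) {
  int npat = pd.npat;
  double *o = &down[(size_t)v * 4 * npat];
  if (v < T.ntip) {
    for (int p = 0; p < npat; ++p) {
      double *x = o + 4 * p;
      x[0] = x[1] = x[2] = x[3] = 0.0;
      x[pd.st[(size_t)v * npat + p]] = 1.0;
    }
    std::fill(&scl[(size_t)v * npat], &scl[(size_t)v * npat] + npat, 0);
    return;
  }
  bool first = true;
  int *sv = &scl[(size_t)v * npat];
  std::fill(sv, sv + npat, 0);
  for (int c : T.ch[v]) {
    edge_contrib(T, pd, down, c, T.el[T.eidx[c]], o, !first);
    const int *sc = &scl[(size_t)c * npat];
    for (int p = 0; p < npat; ++p) sv[p] += sc[p];
    first = false;
  }
  for (int p = 0; p < npat; ++p) {
    double *x = o + 4 * p;
    double m = std::max(std::max(x[0], x[1]), std::max(x[2], x[3]));
    if (m < 1.0 / CD_LIFT && m > 0.0) {
      x[0] *= CD_LIFT; x[1] *= CD_LIFT; x[2] *= CD_LIFT; x[3] *= CD_LIFT;
      sv[p] += 1;
    }
  }
}

double atree_loglik(const ATree &T, const PatternData &pd) {
  int npat = pd.npat;
  std::vector<double> down((size_t)T.nnodes * 4 * npat);
  std::vector<int> scl((size_t)T.nnodes * npat);
  std::vector<int> po;
  T.postorder(po);
  for (int v : po) comp_down(T, pd, down, scl, v);
  const double *r = &down[(size_t)T.root * 4 * npat];
  const int *sr = &scl[(size_t)T.root * npat];
  double ll = 0.0;
  for (int p = 0; p < npat; ++p) {
    const double *l = r + 4 * p;
    double s = l[0] + l[1] + l[2] + l[3];
    ll += pd.w[p] * (std::log(0.25 * s) - sr[p] * CD_LOG_LIFT);
  }
  return ll;
}

PatternData make_patterns(const IntegerMatrix &states,
                          const NumericVector &w) {
  PatternData pd;
  pd.ntip = states.nrow();
  pd.npat = states.ncol();
  pd.st.resize((size_t)pd.ntip * pd.npat);
  for (int t = 0; t < pd.ntip; ++t)
    for (int p = 0; p < pd.npat; ++p)
      pd.st[(size_t)t * pd.npat + p] = states(t, p);
  pd.w.assign(w.begin(), w.end());
  return pd;
}

// maximise sum_p w_p log(b_p + a_p E) over E in [emin, 1]
double opt_E(const std::vector<double> &a, const std::vector<double> &b,
             const std::vector<double> &w, double emin) {
  auto deriv = [&](double E) {
    double d = 0.0;
    for (size_t p = 0; p < a.size(); ++p) d += w[p] * a[p] / (b[p] + a[p] * E);
    return d;
  };
  if (deriv(1.0) >= 0.0) return 1.0;
  if (deriv(emin) <= 0.0) return emin;
  double lo = emin, hi = 1.0, E = 0.5 * (lo + hi);
  for (int it = 0; it < 60; ++it) {
    double d = deriv(E), d2 = 0.0;
    for (size_t p = 0; p < a.size(); ++p) {
      double q = a[p] / (b[p] + a[p] * E);
      d2 -= w[p] * q * q;
    }
    if (d > 0) lo = E; else hi = E;
    double En = E - d / d2;
    if (!(En > lo && En < hi)) En = 0.5 * (lo + hi);
    if (std::fabs(En - E) < 1e-12) { E = En; break; }
    E = En;
  }
  return E;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cd_loglik")]]
double cd_loglik_cpp(IntegerMatrix edge, int ntip, NumericVector el,
                     IntegerMatrix states, NumericVector w) {
  ATree T;
  T.build(edge, ntip, el);
  PatternData pd = make_patterns(states, w);
  return atree_loglik(T, pd);
}

//' @noRd
// [[Rcpp::export(name = ".cd_optim_edges")]]
List cd_optim_edges_cpp(IntegerMatrix edge, int ntip, NumericVector el,
                        IntegerMatrix states, NumericVector w,
                        int max_sweeps = 20, double tol = 1e-8) {
  ATree T;
  T.build(edge, ntip, el);
  PatternData pd = make_patterns(states, w);
  int npat = pd.npat;
  const double EMIN = std::exp(-4.0 / 3.0 * 10.0);  // branch length cap 10

  std::vector<double> down((size_t)T.nnodes * 4 * npat);
  std::vector<int> scl((size_t)T.nnodes * npat);
  std::vector<double> up((size_t)T.nnodes * 4 * npat);
  std::vector<int> po;
  T.postorder(po);

  double prev = atree_loglik(T, pd);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int v : po) comp_down(T, pd, down, scl, v);
    // DFS from the root, optimising each parent edge on the way down
    std::fill(&up[(size_t)T.root * 4 * npat],
              &up[(size_t)T.root * 4 * npat] + 4 * npat, 1.0);
    std::vector<double> pre(4 * npat), A(npat), B(npat), aa(npat), bb(npat);
    std::function<void(int)> visit = [&](int u) {
      for (int c : T.ch[u]) {
        // pre = up[u] (x) product of sibling contributions
        std::copy(&up[(size_t)u * 4 * npat],
                  &up[(size_t)u * 4 * npat] + 4 * npat, pre.begin());
        for (int s : T.ch[u])
          if (s != c)
            edge_contrib(T, pd, down, s, T.el[T.eidx[s]], pre.data(), true);
        // optimise edge (u, c)
        const double *dc = &down[(size_t)c * 4 * npat];
        for (int p = 0; p < npat; ++p) {
          const double *pr = pre.data() + 4 * p;
          const double *l = dc + 4 * p;
          double Sp = pr[0] + pr[1] + pr[2] + pr[3];
          double Sd = l[0] + l[1] + l[2] + l[3];
          double Ap = pr[0] * l[0] + pr[1] * l[1] + pr[2] * l[2] +
                      pr[3] * l[3];
          double Bp = Sp * Sd;
          bb[p] = 0.25 * Bp;
          aa[p] = Ap - 0.25 * Bp;
          // guard against zero rows from normalisation extremes
          if (bb[p] + aa[p] <= 0 && bb[p] <= 0) { aa[p] = 0; bb[p] = 1; }
        }
        double E = opt_E(aa, bb, pd.w, EMIN);
        T.el[T.eidx[c]] = (E >= 1.0) ? 0.0 : -0.75 * std::log(E);
        // up[c] across the freshly optimised edge
        double pdif = 0.25 * (1.0 - E);
        double *uc = &up[(size_t)c * 4 * npat];
        for (int p = 0; p < npat; ++p) {
          const double *pr = pre.data() + 4 * p;
          double Sp = pr[0] + pr[1] + pr[2] + pr[3];
          double base = pdif * Sp;
          double *o = uc + 4 * p;
          o[0] = base + E * pr[0]; o[1] = base + E * pr[1];
          o[2] = base + E * pr[2]; o[3] = base + E * pr[3];
          double m = std::max(std::max(o[0], o[1]), std::max(o[2], o[3]));
          if (m > 0 && (m < 1e-120 || m > 1e120)) {
            o[0] /= m; o[1] /= m; o[2] /= m; o[3] /= m;
          }
        }
        if (c >= T.ntip) {
          visit(c);
          comp_down(T, pd, down, scl, c);  // refresh after sub-edge updates
        }
      }
    };
    visit(T.root);
    double ll = atree_loglik(T, pd);
    if (ll - prev < tol && sweep > 0) { prev = std::max(ll, prev); break; }
    prev = ll;
  }
  return List::create(_["el"] = NumericVector(T.el.begin(), T.el.end()),
                      _["loglik"] = prev);
}

//' @noRd
// [[Rcpp::export(name = ".cd_msc_logdensity")]]
double cd_msc_logdensity_cpp(IntegerVector g_par, NumericVector g_age,
                             IntegerVector g_tipmap, IntegerVector m_par,
                             NumericVector m_tau, NumericVector m_theta) {
  int nn = g_par.size();
  int ntip = (nn + 1) / 2;
  GTree g;
  g.init(ntip);
  for (int v = 0; v < nn; ++v) { g.par[v] = g_par[v]; g.age[v] = g_age[v]; }
  g.rebuild_children();
  ModelTree M;
  M.ntip = (m_par.size() + 1) / 2;
  M.par.assign(m_par.begin(), m_par.end());
  M.tau.assign(m_tau.begin(), m_tau.end());
  M.theta.assign(m_theta.begin(), m_theta.end());
  M.rebuild();
  std::vector<int> tipmap(g_tipmap.begin(), g_tipmap.end());
  return cd_msc_logdensity(g, M, tipmap);
}
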