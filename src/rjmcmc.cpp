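// Reversible-jump MCMC for Bayesian species delimitation on a fixed guide
// tree. Delimitation models are ancestor-closed sets of "split" interior
// nodes; collapsed subtrees merge their populations into one species. The
// state holds per-locus gene trees (clock, with ages), the split indicators,
// divergence times tau for split nodes, and population sizes theta for every
// current lineage. Priors: tau0 ~ G(a_tau, b_tau); non-root split ages given
// tau0 uniform on the order polytope (density prod(h_v) / tau0^k); theta ~
// G(a_th, b_th) iid; delimitation model uniform over the enumerated models
// (or proportional to the number of ranked histories, by option).
//
// The split move draws tau_v ~ U(0, U) with U the exact upper bound (parent
// tau and the youngest gene coalescence that would join the two daughter
// groups) and the two new thetas from their prior, so the theta prior and
// proposal densities cancel in the acceptance ratio.
#include "ctree.h"
using namespace Rcpp;

namespace {

struct Locus {
  GTree g;
  PatternData pd;
  Partials P;
  double seqll;
};

struct RjState {
  // guide tree (fixed)
  int P, nnode, root;
  std::vector<int> par, ch1, ch2, depth;
  std::vector<uint32_t> gmask;       // pop bitmask below each guide node
  // delimitation state
  std::vector<int> split;            // 0/1 per node (tips always 0)
  std::vector<double> tau, theta;
  std::vector<Locus> loci;
  // caches rebuilt whenever the split set changes
  ModelTree M;                        // contracted model tree
  std::vector<int> act, idmap;        // active nodes; guide node -> model id
  std::vector<std::vector<int>> tipmaps;  // per locus: gene tip -> model id
  // per-locus gene masks, invalidated on gene-topology changes
  std::vector<std::vector<uint32_t>> gmasks;
  std::vector<char> gmask_ok;
  bool lik_off;
  double a_tau, b_tau, a_th, b_th;
  int model_prior;                   // 0 uniform, 1 ~ #ranked histories

  bool active(int v) const { return v == root || split[par[v]]; }
  bool is_tip(int v) const { return v < P; }

  // current species (lineage node) holding population p
  int cur(int p) const {
    int v = p;
    while (v != root && !split[par[v]]) v = par[v];
    return v;
  }
  // lowest guide node whose tip set contains `mask`
  int mrca_of_mask(uint32_t mask) const {
    int p = 0;
    while (!(mask & (1u << p))) p++;
    int v = p;
    while ((gmask[v] & mask) != mask) v = par[v];
    return v;
  }
};

int unif_int(int n) {
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void gene_masks(const RjState &st, const GTree &g, std::vector<uint32_t> &m) {
  m.assign(g.nnode, 0);
  for (int t = 0; t < g.ntip; ++t) m[t] = 1u << g.pop[t];
  std::vector<int> po;
  g.postorder_internal(po);
  for (int v : po) m[v] = m[g.ch1[v]] | m[g.ch2[v]];
}

// rebuild the contracted model tree + per-locus tip maps (split set changed)
void refresh_model(RjState &st) {
  st.idmap.assign(st.nnode, -1);
  st.act.clear();
  for (int v = 0; v < st.nnode; ++v)
    if (st.active(v)) { st.idmap[v] = (int)st.act.size(); st.act.push_back(v); }
  ModelTree &M = st.M;
  M.ntip = 0;
  M.par.resize(st.act.size());
  M.tau.resize(st.act.size());
  M.theta.resize(st.act.size());
  for (size_t i = 0; i < st.act.size(); ++i) {
    int v = st.act[i];
    M.par[i] = (v == st.root) ? -1 : st.idmap[st.par[v]];
    if (!st.split[v]) M.ntip++;
  }
  M.rebuild();
  std::vector<int> curof(st.P);
  for (int p = 0; p < st.P; ++p) curof[p] = st.idmap[st.cur(p)];
  st.tipmaps.resize(st.loci.size());
  for (size_t l = 0; l < st.loci.size(); ++l) {
    Locus &lc = st.loci[l];
    st.tipmaps[l].resize(lc.g.ntip);
    for (int t = 0; t < lc.g.ntip; ++t)
      st.tipmaps[l][t] = curof[lc.g.pop[t]];
  }
}

// total MSC log density; parameters are refreshed from the state each call
double msc_total(RjState &st) {
  ModelTree &M = st.M;
  for (size_t i = 0; i < st.act.size(); ++i) {
    int v = st.act[i];
    M.tau[i] = st.split[v] ? st.tau[v] : 0.0;
    M.theta[i] = st.theta[v];
  }
  double tot = 0.0;
  for (size_t l = 0; l < st.loci.size(); ++l) {
    double d = cd_msc_logdensity(st.loci[l].g, M, st.tipmaps[l]);
    if (d == CD_NEG_INF) return CD_NEG_INF;
    tot += d;
  }
  return tot;
}

const std::vector<uint32_t> &locus_masks(RjState &st, int l) {
  if (!st.gmask_ok[l]) {
    gene_masks(st, st.loci[l].g, st.gmasks[l]);
    st.gmask_ok[l] = 1;
  }
  return st.gmasks[l];
}

// log prior of the divergence times under the current model
double logp_tau(const RjState &st) {
  if (!st.split[st.root]) return 0.0;
  double t0 = st.tau[st.root];
  double lp = R::dgamma(t0, st.a_tau, 1.0 / st.b_tau, 1);
  // h_v = number of split non-root nodes in subtree(v), hook-length form
  int k = 0;
  std::vector<int> h(st.nnode, 0);
  // process nodes deepest-first so children are done before parents
  std::vector<int> idx(st.nnode);
  for (int v = 0; v < st.nnode; ++v) idx[v] = v;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return st.depth[a] > st.depth[b];
  });
  for (int v : idx) {
    if (st.is_tip(v) || !st.split[v]) continue;
    h[v] = 1 + h[st.ch1[v]] + h[st.ch2[v]];
    if (v != st.root) {
      k++;
      lp += std::log((double)h[v]);
    }
  }
  lp -= k * std::log(t0);
  return lp;
}

// log model prior up to a constant shared by all models
double logp_model(const RjState &st) {
  if (st.model_prior == 0) return 0.0;
  // weight ~ number of ranked histories of the model tree: s! / prod r_v
  int s = 0;
  std::vector<int> r(st.nnode, 0), idx(st.nnode);
  for (int v = 0; v < st.nnode; ++v) idx[v] = v;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return st.depth[a] > st.depth[b];
  });
  double lp = 0.0;
  for (int v : idx) {
    if (st.is_tip(v) || !st.split[v]) continue;
    r[v] = 1 + r[st.ch1[v]] + r[st.ch2[v]];
    s++;
    lp -= std::log((double)r[v]);
  }
  lp += std::lgamma(s + 1.0);
  return lp;
}

double logp_theta(const RjState &st) {
  double lp = 0.0;
  for (int v = 0; v < st.nnode; ++v)
    if (st.active(v)) lp += R::dgamma(st.theta[v], st.a_th, 1.0 / st.b_th, 1);
  return lp;
}

// exact upper bound for tau_v: parent tau and the youngest gene coalescence
// whose descendants lie inside subtree(v) and span both daughter groups
double split_upper_bound(RjState &st, int v) {
  double U = (v != st.root && st.split[st.par[v]]) ? st.tau[st.par[v]]
                                                   : R_PosInf;
  uint32_t m1 = st.gmask[st.ch1[v]], m2 = st.gmask[st.ch2[v]];
  uint32_t sub = st.gmask[v];
  for (size_t l = 0; l < st.loci.size(); ++l) {
    const std::vector<uint32_t> &gm = locus_masks(st, (int)l);
    const Locus &lc = st.loci[l];
    for (int g = lc.g.ntip; g < lc.g.nnode; ++g) {
      uint32_t m = gm[g];
      if ((m & ~sub) == 0 && (m & m1) && (m & m2))
        U = std::min(U, lc.g.age[g]);
    }
  }
  return U;
}

struct Tuner {
  double eps;
  int acc = 0, tries = 0;
  explicit Tuner(double e) : eps(e) {}
  void update(bool accepted, bool tuning) {
    if (!tuning) return;
    tries++; if (accepted) acc++;
    if (tries >= 100) {
      eps *= std::exp(1.5 * ((double)acc / tries - 0.30));
      eps = std::min(std::max(eps, 1e-4), 20.0);
      acc = 0; tries = 0;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cd_rjmcmc")]]
List cd_rjmcmc(List loci, IntegerVector guide_par, LogicalVector split0,
               NumericVector tau0, NumericVector theta0, double a_tau,
               double b_tau, double a_th, double b_th, int model_prior,
               int burnin, int nsamples, int sample_every,
               bool likelihood_off, bool check_states) {
  RjState st;
  st.nnode = guide_par.size();
  st.P = (st.nnode + 1) / 2;
  st.par.assign(guide_par.begin(), guide_par.end());
  st.lik_off = likelihood_off;
  st.a_tau = a_tau; st.b_tau = b_tau; st.a_th = a_th; st.b_th = b_th;
  st.model_prior = model_prior;
  st.ch1.assign(st.nnode, -1); st.ch2.assign(st.nnode, -1);
  st.root = -1;
  for (int v = 0; v < st.nnode; ++v) {
    if (st.par[v] < 0) { st.root = v; continue; }
    if (st.ch1[st.par[v]] < 0) st.ch1[st.par[v]] = v;
    else st.ch2[st.par[v]] = v;
  }
  st.depth.assign(st.nnode, 0);
  {
    std::vector<int> stack{st.root};
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (st.ch1[v] >= 0) {
        st.depth[st.ch1[v]] = st.depth[v] + 1;
        st.depth[st.ch2[v]] = st.depth[v] + 1;
        stack.push_back(st.ch1[v]); stack.push_back(st.ch2[v]);
      }
    }
  }
  st.gmask.assign(st.nnode, 0);
  {
    std::vector<int> idx(st.nnode);
    for (int v = 0; v < st.nnode; ++v) idx[v] = v;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return st.depth[a] > st.depth[b];
    });
    for (int v : idx)
      st.gmask[v] = st.is_tip(v) ? (1u << v)
                                 : (st.gmask[st.ch1[v]] | st.gmask[st.ch2[v]]);
  }
  st.split.assign(split0.begin(), split0.end());
  st.tau.assign(tau0.begin(), tau0.end());
  st.theta.assign(theta0.begin(), theta0.end());

  st.loci.resize(loci.size());
  for (int l = 0; l < loci.size(); ++l) {
    List L = loci[l];
    IntegerMatrix states = L["state"];
    NumericVector w = L["w"];
    IntegerVector pop = L["pop"];
    IntegerVector gpar = L["par"];
    NumericVector gage = L["age"];
    Locus &lc = st.loci[l];
    int ntip = states.nrow();
    lc.g.init(ntip);
    for (int v = 0; v < lc.g.nnode; ++v) {
      lc.g.par[v] = gpar[v]; lc.g.age[v] = gage[v];
    }
    for (int t = 0; t < ntip; ++t) lc.g.pop[t] = pop[t];
    lc.g.rebuild_children();
    lc.pd.ntip = ntip; lc.pd.npat = states.ncol();
    lc.pd.st.resize((size_t)ntip * lc.pd.npat);
    for (int t = 0; t < ntip; ++t)
      for (int p = 0; p < lc.pd.npat; ++p)
        lc.pd.st[(size_t)t * lc.pd.npat + p] = states(t, p);
    lc.pd.w.assign(w.begin(), w.end());
    lc.P.init(ntip, lc.pd.npat);
    lc.seqll = st.lik_off ? 0.0 : cd_full_loglik(lc.g, lc.pd, lc.P);
  }

  st.gmasks.resize(st.loci.size());
  st.gmask_ok.assign(st.loci.size(), 0);
  refresh_model(st);
  double msc = msc_total(st);
  if (msc == CD_NEG_INF)
    stop("initial gene trees incompatible with initial delimitation state");

  Tuner tun_root(1.3), tun_theta(1.0), tun_scale(0.2);
  int acc_rj = 0, try_rj = 0;
  int acc_scale = 0, try_scale = 0, acc_th = 0, try_th = 0;

  int total_sweeps = burnin + nsamples * sample_every;
  IntegerMatrix out_split(nsamples, st.nnode);
  NumericVector out_tau0(nsamples), out_th0(nsamples), out_lp(nsamples);
  int nsamp = 0;

  for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
    bool tuning = sweep <= burnin;

    // ---- reversible-jump split/merge ----
    {
      std::vector<int> can_split, can_merge;
      for (int v = st.P; v < st.nnode; ++v) {
        if (!st.split[v] && st.active(v)) can_split.push_back(v);
        if (st.split[v] &&
            (st.is_tip(st.ch1[v]) || !st.split[st.ch1[v]]) &&
            (st.is_tip(st.ch2[v]) || !st.split[st.ch2[v]]))
          can_merge.push_back(v);
      }
      bool do_split;
      double p_fwd;
      if (can_split.empty() && can_merge.empty()) {
        do_split = false; p_fwd = 0;  // single-node guide tree: nothing to do
      } else if (can_split.empty()) { do_split = false; p_fwd = 1.0; }
      else if (can_merge.empty()) { do_split = true; p_fwd = 1.0; }
      else { do_split = R::unif_rand() < 0.5; p_fwd = 0.5; }

      if (p_fwd > 0 && do_split) {
        try_rj++;
        int v = can_split[unif_int((int)can_split.size())];
        double U = split_upper_bound(st, v);
        if (U > 0 && R_finite(U)) {
          double old_msc = msc, old_pt = logp_tau(st), old_pm = logp_model(st);
          double tau_new = U * R::unif_rand();
          double th1 = R::rgamma(st.a_th, 1.0 / st.b_th);
          double th2 = R::rgamma(st.a_th, 1.0 / st.b_th);
          double old_th1 = st.theta[st.ch1[v]], old_th2 = st.theta[st.ch2[v]];
          st.split[v] = 1; st.tau[v] = tau_new;
          st.theta[st.ch1[v]] = th1; st.theta[st.ch2[v]] = th2;
          refresh_model(st);
          // reverse merge selection probability in the new state
          int n_merge_new = 0;
          for (int x = st.P; x < st.nnode; ++x)
            if (st.split[x] &&
                (st.is_tip(st.ch1[x]) || !st.split[st.ch1[x]]) &&
                (st.is_tip(st.ch2[x]) || !st.split[st.ch2[x]]))
              n_merge_new++;
          bool split_left = false;
          for (int x = st.P; x < st.nnode; ++x)
            if (!st.split[x] && st.active(x)) { split_left = true; break; }
          double p_rev = split_left ? 0.5 : 1.0;
          double new_msc = msc_total(st);
          double lr = (new_msc - old_msc) + (logp_tau(st) - old_pt) +
                      (logp_model(st) - old_pm) + std::log(U) +
                      std::log(p_rev / (double)n_merge_new) -
                      std::log(p_fwd / (double)can_split.size());
          if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
            msc = new_msc; acc_rj++;
          } else {
            st.split[v] = 0; st.tau[v] = 0;
            st.theta[st.ch1[v]] = old_th1; st.theta[st.ch2[v]] = old_th2;
            refresh_model(st);
          }
        }
      } else if (p_fwd > 0) {  // merge
        try_rj++;
        int v = can_merge[unif_int((int)can_merge.size())];
        double U = split_upper_bound(st, v);
        if (st.tau[v] < U) {  // reverse split must be able to propose tau_v
          double old_msc = msc, old_pt = logp_tau(st), old_pm = logp_model(st);
          double old_tau = st.tau[v];
          double old_th1 = st.theta[st.ch1[v]], old_th2 = st.theta[st.ch2[v]];
          st.split[v] = 0; st.tau[v] = 0;
          st.theta[st.ch1[v]] = NA_REAL; st.theta[st.ch2[v]] = NA_REAL;
          refresh_model(st);
          int n_split_new = 0;
          for (int x = st.P; x < st.nnode; ++x)
            if (!st.split[x] && st.active(x)) n_split_new++;
          bool merge_left = false;
          for (int x = st.P; x < st.nnode; ++x)
            if (st.split[x] &&
                (st.is_tip(st.ch1[x]) || !st.split[st.ch1[x]]) &&
                (st.is_tip(st.ch2[x]) || !st.split[st.ch2[x]]))
              { merge_left = true; break; }
          double p_rev = merge_left ? 0.5 : 1.0;
          double new_msc = msc_total(st);
          double lr = (new_msc - old_msc) + (logp_tau(st) - old_pt) +
                      (logp_model(st) - old_pm) - std::log(U) +
                      std::log(p_rev / (double)n_split_new) -
                      std::log(p_fwd / (double)can_merge.size());
          if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
            msc = new_msc; acc_rj++;
          } else {
            st.split[v] = 1; st.tau[v] = old_tau;
            st.theta[st.ch1[v]] = old_th1; st.theta[st.ch2[v]] = old_th2;
            refresh_model(st);
          }
        }
      }
    }

    // ---- gene-tree node ages ----
    for (size_t l = 0; l < st.loci.size(); ++l) {
      Locus &lc = st.loci[l];
      const std::vector<uint32_t> &gm = locus_masks(st, (int)l);
      for (int v = lc.g.ntip; v < lc.g.nnode; ++v) {
        int m0 = st.mrca_of_mask(gm[v]);
        double floor_tau = st.split[m0] ? st.tau[m0] : 0.0;
        double lo = std::max(std::max(lc.g.age[lc.g.ch1[v]],
                                      lc.g.age[lc.g.ch2[v]]), floor_tau);
        if (v == lc.g.root) {
          double c = std::exp(tun_root.eps * (R::unif_rand() - 0.5));
          double prop = lc.g.age[v] * c;
          bool accepted = false;
          if (prop > lo) {
            double old_age = lc.g.age[v], old_seq = lc.seqll, old_msc = msc;
                        lc.g.age[v] = prop;
            double new_seq =
                st.lik_off ? 0.0 : cd_update_path(lc.g, lc.pd, lc.P, v);
            double new_msc = msc_total(st);
            double lr = (new_seq - old_seq) + (new_msc - old_msc) + std::log(c);
            if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
              lc.seqll = new_seq; msc = new_msc; accepted = true;
            } else {
              lc.g.age[v] = old_age;
              if (!st.lik_off) cd_update_path(lc.g, lc.pd, lc.P, v);
            }
          }
          tun_root.update(accepted, tuning);
        } else {
          double hi = lc.g.age[lc.g.par[v]];
          if (hi <= lo) continue;
          double old_age = lc.g.age[v], old_seq = lc.seqll, old_msc = msc;
                    lc.g.age[v] = lo + R::unif_rand() * (hi - lo);
          double new_seq =
              st.lik_off ? 0.0 : cd_update_path(lc.g, lc.pd, lc.P, v);
          double new_msc = msc_total(st);
          double lr = (new_seq - old_seq) + (new_msc - old_msc);
          if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
            lc.seqll = new_seq; msc = new_msc;
          } else {
            lc.g.age[v] = old_age;
            if (!st.lik_off) cd_update_path(lc.g, lc.pd, lc.P, v);
          }
        }
      }
    }

    // ---- gene-tree topology: two narrow + one wide exchange per locus ----
    for (size_t l = 0; l < st.loci.size(); ++l) {
      Locus &lc = st.loci[l];
      if (lc.g.ntip < 3) continue;
      for (int rep = 0; rep < 2; ++rep) {
        int v = lc.g.ntip + unif_int(lc.g.ntip - 1);
        if (v == lc.g.root) continue;
        int w = lc.g.par[v];
        int sib = (lc.g.ch1[w] == v) ? lc.g.ch2[w] : lc.g.ch1[w];
        int c = (R::unif_rand() < 0.5) ? lc.g.ch1[v] : lc.g.ch2[v];
        if (lc.g.age[v] <= lc.g.age[sib]) continue;
        double old_seq = lc.seqll, old_msc = msc;
                if (lc.g.ch1[v] == c) lc.g.ch1[v] = sib; else lc.g.ch2[v] = sib;
        if (lc.g.ch1[w] == sib) lc.g.ch1[w] = c; else lc.g.ch2[w] = c;
        lc.g.par[sib] = v; lc.g.par[c] = w;
        double new_seq =
            st.lik_off ? 0.0 : cd_update_path(lc.g, lc.pd, lc.P, v);
        double new_msc = msc_total(st);
        double lr = (new_seq - old_seq) + (new_msc - old_msc);
        if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
          lc.seqll = new_seq; msc = new_msc;
          st.gmask_ok[l] = 0;
        } else {
          if (lc.g.ch1[v] == sib) lc.g.ch1[v] = c; else lc.g.ch2[v] = c;
          if (lc.g.ch1[w] == c) lc.g.ch1[w] = sib; else lc.g.ch2[w] = sib;
          lc.g.par[sib] = w; lc.g.par[c] = v;
          if (!st.lik_off) cd_update_path(lc.g, lc.pd, lc.P, v);
        }
      }
      if (lc.g.ntip >= 4) {
        int a = unif_int(lc.g.nnode), b = unif_int(lc.g.nnode);
        if (a != b && a != lc.g.root && b != lc.g.root &&
            lc.g.par[a] != lc.g.par[b] && !lc.g.is_ancestor(a, b) &&
            !lc.g.is_ancestor(b, a) &&
            lc.g.age[lc.g.par[b]] > lc.g.age[a] &&
            lc.g.age[lc.g.par[a]] > lc.g.age[b]) {
          int pa = lc.g.par[a], pb = lc.g.par[b];
          double old_seq = lc.seqll, old_msc = msc;

          if (lc.g.ch1[pa] == a) lc.g.ch1[pa] = b; else lc.g.ch2[pa] = b;
          if (lc.g.ch1[pb] == b) lc.g.ch1[pb] = a; else lc.g.ch2[pb] = a;
          lc.g.par[a] = pb; lc.g.par[b] = pa;
          double new_seq =
              st.lik_off ? 0.0 : cd_full_loglik(lc.g, lc.pd, lc.P);
          double new_msc = msc_total(st);
          double lr = (new_seq - old_seq) + (new_msc - old_msc);
          if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
            lc.seqll = new_seq; msc = new_msc;
            st.gmask_ok[l] = 0;
          } else {
            if (lc.g.ch1[pa] == b) lc.g.ch1[pa] = a; else lc.g.ch2[pa] = a;
            if (lc.g.ch1[pb] == a) lc.g.ch1[pb] = b; else lc.g.ch2[pb] = b;
            lc.g.par[a] = pa; lc.g.par[b] = pb;
            if (!st.lik_off) cd_full_loglik(lc.g, lc.pd, lc.P);
          }
        }
      }
    }

    // ---- divergence-time slides for split nodes ----
    for (int v = st.P; v < st.nnode; ++v) {
      if (!st.split[v]) continue;
      double lo = 0.0;
      for (int c : {st.ch1[v], st.ch2[v]})
        if (!st.is_tip(c) && st.split[c]) lo = std::max(lo, st.tau[c]);
      double hi = (v != st.root) ? st.tau[st.par[v]] : R_PosInf;
      // youngest gene coalescence whose model MRCA is exactly v
      uint32_t m1 = st.gmask[st.ch1[v]], m2 = st.gmask[st.ch2[v]];
      uint32_t sub = st.gmask[v];
      for (size_t l = 0; l < st.loci.size(); ++l) {
        const std::vector<uint32_t> &gm = locus_masks(st, (int)l);
        const Locus &lc = st.loci[l];
        for (int g = lc.g.ntip; g < lc.g.nnode; ++g) {
          uint32_t m = gm[g];
          if ((m & ~sub) == 0 && (m & m1) && (m & m2))
            hi = std::min(hi, lc.g.age[g]);
        }
      }
      if (hi <= lo) continue;
      double old_tau = st.tau[v], old_msc = msc;
      double old_pt = (v == st.root) ? logp_tau(st) : 0.0;
      st.tau[v] = lo + R::unif_rand() * (hi - lo);
      double new_msc = msc_total(st);
      double d_pt = (v == st.root) ? (logp_tau(st) - old_pt) : 0.0;
      if (new_msc != CD_NEG_INF &&
          std::log(R::unif_rand()) < (new_msc - old_msc) + d_pt) {
        msc = new_msc;
      } else st.tau[v] = old_tau;
    }

    // ---- theta multipliers ----
    for (int v = 0; v < st.nnode; ++v) {
      if (!st.active(v)) continue;
      double c = std::exp(tun_theta.eps * (R::unif_rand() - 0.5));
      double prop = st.theta[v] * c;
      double old_theta = st.theta[v], old_msc = msc;
      st.theta[v] = prop;
      double new_msc = msc_total(st);
      double lr = (new_msc - old_msc) + std::log(c) +
                  R::dgamma(prop, st.a_th, 1.0 / st.b_th, 1) -
                  R::dgamma(old_theta, st.a_th, 1.0 / st.b_th, 1);
      bool accepted = new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr;
      if (accepted) msc = new_msc; else st.theta[v] = old_theta;
      tun_theta.update(accepted, tuning);
      if (!tuning) { try_th++; if (accepted) acc_th++; }
    }

    // ---- coordinated scale ("mixing") move ----
    {
      double c = std::exp(tun_scale.eps * (R::unif_rand() - 0.5));
      int D = 0;
      for (int v = st.P; v < st.nnode; ++v) if (st.split[v]) D++;
      for (int v = 0; v < st.nnode; ++v) if (st.active(v)) D++;
      for (auto &lc : st.loci) D += lc.g.ntip - 1;
      double old_msc = msc, old_pt = logp_tau(st), old_pth = logp_theta(st);
      double old_seq = 0;
      std::vector<double> old_ll(st.loci.size());
      for (size_t l = 0; l < st.loci.size(); ++l) {
        old_ll[l] = st.loci[l].seqll; old_seq += old_ll[l];
      }
      for (int v = st.P; v < st.nnode; ++v) if (st.split[v]) st.tau[v] *= c;
      for (int v = 0; v < st.nnode; ++v) if (st.active(v)) st.theta[v] *= c;
      for (auto &lc : st.loci)
        for (int v = lc.g.ntip; v < lc.g.nnode; ++v) lc.g.age[v] *= c;
      double new_seq = 0;
      for (auto &lc : st.loci) {
        lc.seqll = st.lik_off ? 0.0 : cd_full_loglik(lc.g, lc.pd, lc.P);
        new_seq += lc.seqll;
      }
      double new_msc = msc_total(st);
      double lr = (new_seq - old_seq) + (new_msc - old_msc) +
                  (logp_tau(st) - old_pt) + (logp_theta(st) - old_pth) +
                  D * std::log(c);
      bool accepted = new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr;
      if (accepted) {
        msc = new_msc;
      } else {
        for (int v = st.P; v < st.nnode; ++v) if (st.split[v]) st.tau[v] /= c;
        for (int v = 0; v < st.nnode; ++v) if (st.active(v)) st.theta[v] /= c;
        for (size_t l = 0; l < st.loci.size(); ++l) {
          Locus &lc = st.loci[l];
          for (int v = lc.g.ntip; v < lc.g.nnode; ++v) lc.g.age[v] /= c;
          lc.seqll = old_ll[l];
          if (!st.lik_off) cd_full_loglik(lc.g, lc.pd, lc.P);
        }
      }
      tun_scale.update(accepted, tuning);
      if (!tuning) { try_scale++; if (accepted) acc_scale++; }
    }

    // ---- sampling ----
    if (sweep > burnin && (sweep - burnin) % sample_every == 0 &&
        nsamp < nsamples) {
      if (check_states) {
        for (int v = st.P; v < st.nnode; ++v)
          if (st.split[v] && v != st.root && !st.split[st.par[v]])
            stop("ancestor closure violated in sampled state");
        if (msc_total(st) == CD_NEG_INF)
          stop("sampled state incompatible with gene trees");
      }
      for (int v = 0; v < st.nnode; ++v) out_split(nsamp, v) = st.split[v];
      out_tau0[nsamp] = st.split[st.root] ? st.tau[st.root] : 0.0;
      out_th0[nsamp] = st.theta[st.root];
      double tot = 0;
      for (auto &lc : st.loci) tot += lc.seqll;
      out_lp[nsamp] = tot + msc;
      nsamp++;
    }
  }

  return List::create(
      _["split"] = out_split, _["tau_root"] = out_tau0,
      _["theta_root"] = out_th0, _["logpost"] = out_lp,
      _["acc_rj"] = try_rj > 0 ? (double)acc_rj / try_rj : NA_REAL,
      _["acc_theta"] = try_th > 0 ? (double)acc_th / try_th : NA_REAL,
      _["acc_scale"] = try_scale > 0 ? (double)acc_scale / try_scale : NA_REAL,
      _["eps"] = NumericVector::create(tun_root.eps, tun_theta.eps,
                                       tun_scale.eps),
      _["final_split"] = IntegerVector(st.split.begin(), st.split.end()),
      _["final_tau"] = NumericVector(st.tau.begin(), st.tau.end()),
      _["final_theta"] = NumericVector(st.theta.begin(), st.theta.end()));
}
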