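// Bayesian species-tree MCMC under the multispecies coalescent with a Yule
// prior on the species tree, f(lambda) = 1/lambda, and a truncated f(theta) =
// 1/theta prior on population sizes. Gene trees for each locus are part of
// the state; sequence likelihoods use JC69 pruning with cached partials.
#include "ctree.h"
#include <functional>
using namespace Rcpp;

namespace {

struct Locus {
  GTree g;
  PatternData pd;
  Partials P;
  double seqll;
};

static const double LAM_LO = 1e-2, LAM_HI = 1e6;

struct SpState {
  ModelTree S;
  double lambda;
  std::vector<Locus> loci;
  bool lik_off;
  double th_lo, th_hi;
  // cached per-locus gene-node origins (species-tree MRCA of descendants);
  // valid until a gene-tree or species-tree topology change
  std::vector<std::vector<int>> origins;
  std::vector<char> ori_ok;
};

int unif_int(int n) {
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// model-tree MRCA of the populations below gene node v (subtree walk)
int origin_of(const GTree &g, const ModelTree &M, int v) {
  int m = -1;
  static thread_local std::vector<int> stack;
  stack.clear();
  stack.push_back(v);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    if (u < g.ntip) {
      m = (m < 0) ? g.pop[u] : M.mrca(m, g.pop[u]);
    } else {
      stack.push_back(g.ch1[u]); stack.push_back(g.ch2[u]);
    }
  }
  return m;
}

// origins of all internal gene nodes (postorder fill)
void all_origins(const GTree &g, const ModelTree &M, std::vector<int> &ori) {
  ori.assign(g.nnode, -1);
  for (int t = 0; t < g.ntip; ++t) ori[t] = g.pop[t];
  static thread_local std::vector<int> po;
  g.postorder_internal(po);
  for (int v : po) ori[v] = M.mrca(ori[g.ch1[v]], ori[g.ch2[v]]);
}

const std::vector<int> &locus_origins(SpState &st, int l) {
  if (!st.ori_ok[l]) {
    all_origins(st.loci[l].g, st.S, st.origins[l]);
    st.ori_ok[l] = 1;
  }
  return st.origins[l];
}

void invalidate_origins(SpState &st) {
  std::fill(st.ori_ok.begin(), st.ori_ok.end(), 0);
}

double msc_total(SpState &st) {
  double d = 0.0;
  for (auto &lc : st.loci) {
    double x = cd_msc_logdensity(lc.g, st.S, lc.g.pop);
    if (x == CD_NEG_INF) return CD_NEG_INF;
    d += x;
  }
  return d;
}

// min gene-node age whose origin (under M) equals species node k
double min_age_with_origin(SpState &st, int k) {
  double m = R_PosInf;
  for (size_t l = 0; l < st.loci.size(); ++l) {
    const std::vector<int> &ori = locus_origins(st, (int)l);
    const Locus &lc = st.loci[l];
    for (int v = lc.g.ntip; v < lc.g.nnode; ++v)
      if (ori[v] == k) m = std::min(m, lc.g.age[v]);
  }
  return m;
}

struct Tuner {
  double eps;
  int acc = 0, tries = 0;
  explicit Tuner(double e) : eps(e) {}
  void update(bool accepted, bool tuning) {
    if (!tuning) return;
    tries++; if (accepted) acc++;
    if (tries >= 100) {
      double rate = (double)acc / tries;
      eps *= std::exp(1.5 * (rate - 0.30));
      eps = std::min(std::max(eps, 1e-4), 20.0);
      acc = 0; tries = 0;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cd_sptree_mcmc")]]
List cd_sptree_mcmc(List loci, IntegerVector sp_par, NumericVector sp_tau,
                    NumericVector sp_theta, double lambda0, double th_lo,
                    double th_hi, int niter, int burnin, int sample_every,
                    bool likelihood_off, double root_age_bound) {
  SpState st;
  st.lambda = lambda0;
  st.lik_off = likelihood_off;
  st.th_lo = th_lo; st.th_hi = th_hi;
  st.S.ntip = (sp_par.size() + 1) / 2;
  st.S.par.assign(sp_par.begin(), sp_par.end());
  st.S.tau.assign(sp_tau.begin(), sp_tau.end());
  st.S.theta.assign(sp_theta.begin(), sp_theta.end());
  st.S.rebuild();
  int nsp_nodes = st.S.nnode;

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
      lc.g.par[v] = gpar[v];
      lc.g.age[v] = gage[v];
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

  st.origins.resize(st.loci.size());
  st.ori_ok.assign(st.loci.size(), 0);
  double msc = msc_total(st);
  if (msc == CD_NEG_INF) stop("initial gene trees incompatible with species tree");
  double yule = cd_yule_logprior(st.S, st.lambda);

  const int NMOVES = 9;
  // gene age, gene root, narrow, wide, sp tau, sp NNI, theta, lambda, scale
  double wts[NMOVES] = {0.34, 0.05, 0.16, 0.05, 0.14, 0.11, 0.10, 0.025, 0.025};
  double cum[NMOVES];
  double s = 0;
  for (int i = 0; i < NMOVES; ++i) { s += wts[i]; cum[i] = s; }
  for (int i = 0; i < NMOVES; ++i) cum[i] /= s;
  std::vector<int> acc(NMOVES, 0), tries(NMOVES, 0);
  Tuner tun_root(1.3), tun_theta(0.8), tun_scale(0.15);

  int nsamp_max = niter / std::max(sample_every, 1) + 1;
  IntegerMatrix out_par(nsamp_max, nsp_nodes);
  NumericMatrix out_tau(nsamp_max, nsp_nodes);
  NumericVector out_lambda(nsamp_max), out_ll(nsamp_max);
  int nsamp = 0;

  std::vector<int> ori;

  for (int iter = 1; iter <= niter; ++iter) {
    bool tuning = iter <= burnin;
    double u = R::unif_rand();
    int mv = 0;
    while (mv < NMOVES - 1 && u > cum[mv]) mv++;
    tries[mv]++;
    bool ok = false;

    if (mv == 0) {  // gene internal (non-root) node age, uniform in bounds
      int l = unif_int((int)st.loci.size());
      Locus &lc = st.loci[l];
      if (lc.g.ntip < 3) { continue; }
      int v = lc.g.ntip + unif_int(lc.g.ntip - 1);
      if (v == lc.g.root) continue;
      int m0 = locus_origins(st, l)[v];
      double lo = std::max(std::max(lc.g.age[lc.g.ch1[v]],
                                    lc.g.age[lc.g.ch2[v]]), st.S.tau[m0]);
      double hi = lc.g.age[lc.g.par[v]];
      if (hi <= lo) continue;
      double old_age = lc.g.age[v];
      double prop = lo + R::unif_rand() * (hi - lo);
      double old_seq = lc.seqll, old_msc = msc;
            lc.g.age[v] = prop;
      double new_seq = st.lik_off ? 0.0 : cd_update_path(lc.g, lc.pd, lc.P, v);
      double new_msc = msc_total(st);
      double lr = (new_seq - old_seq) + (new_msc - old_msc);
      if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
        lc.seqll = new_seq; msc = new_msc; ok = true;
      } else {
        lc.g.age[v] = old_age;
        if (!st.lik_off) cd_update_path(lc.g, lc.pd, lc.P, v);
      }
    } else if (mv == 1) {  // gene root age multiplier
      int l = unif_int((int)st.loci.size());
      Locus &lc = st.loci[l];
      int v = lc.g.root;
      double c = std::exp(tun_root.eps * (R::unif_rand() - 0.5));
      double prop = lc.g.age[v] * c;
      int m0 = locus_origins(st, l)[v];
      double lo = std::max(std::max(lc.g.age[lc.g.ch1[v]],
                                    lc.g.age[lc.g.ch2[v]]), st.S.tau[m0]);
      bool accepted = false;
      if (prop > lo) {
        double old_age = lc.g.age[v], old_seq = lc.seqll, old_msc = msc;
                lc.g.age[v] = prop;
        double new_seq = st.lik_off ? 0.0 : cd_update_path(lc.g, lc.pd, lc.P, v);
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
      ok = accepted;
    } else if (mv == 2) {  // narrow exchange on a gene tree
      int l = unif_int((int)st.loci.size());
      Locus &lc = st.loci[l];
      if (lc.g.ntip < 3) continue;
      int v = lc.g.ntip + unif_int(lc.g.ntip - 1);
      if (v == lc.g.root) continue;
      int w = lc.g.par[v];
      int sib = (lc.g.ch1[w] == v) ? lc.g.ch2[w] : lc.g.ch1[w];
      int c = (R::unif_rand() < 0.5) ? lc.g.ch1[v] : lc.g.ch2[v];
      if (lc.g.age[v] <= lc.g.age[sib]) continue;
      double old_seq = lc.seqll, old_msc = msc;
            // swap sib and c
      if (lc.g.ch1[v] == c) lc.g.ch1[v] = sib; else lc.g.ch2[v] = sib;
      if (lc.g.ch1[w] == sib) lc.g.ch1[w] = c; else lc.g.ch2[w] = c;
      lc.g.par[sib] = v; lc.g.par[c] = w;
      double new_seq = st.lik_off ? 0.0 : cd_update_path(lc.g, lc.pd, lc.P, v);
      double new_msc = msc_total(st);
      double lr = (new_seq - old_seq) + (new_msc - old_msc);
      if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
        lc.seqll = new_seq; msc = new_msc; ok = true;
        st.ori_ok[l] = 0;
      } else {
        if (lc.g.ch1[v] == sib) lc.g.ch1[v] = c; else lc.g.ch2[v] = c;
        if (lc.g.ch1[w] == c) lc.g.ch1[w] = sib; else lc.g.ch2[w] = sib;
        lc.g.par[sib] = w; lc.g.par[c] = v;
        if (!st.lik_off) cd_update_path(lc.g, lc.pd, lc.P, v);
      }
    } else if (mv == 3) {  // wide exchange on a gene tree
      int l = unif_int((int)st.loci.size());
      Locus &lc = st.loci[l];
      if (lc.g.ntip < 4) continue;
      int a = unif_int(lc.g.nnode), b = unif_int(lc.g.nnode);
      if (a == b || a == lc.g.root || b == lc.g.root) continue;
      if (lc.g.par[a] == lc.g.par[b]) continue;
      if (lc.g.is_ancestor(a, b) || lc.g.is_ancestor(b, a)) continue;
      if (lc.g.age[lc.g.par[b]] <= lc.g.age[a] ||
          lc.g.age[lc.g.par[a]] <= lc.g.age[b]) continue;
      int pa = lc.g.par[a], pb = lc.g.par[b];
      double old_seq = lc.seqll, old_msc = msc;

      if (lc.g.ch1[pa] == a) lc.g.ch1[pa] = b; else lc.g.ch2[pa] = b;
      if (lc.g.ch1[pb] == b) lc.g.ch1[pb] = a; else lc.g.ch2[pb] = a;
      lc.g.par[a] = pb; lc.g.par[b] = pa;
      double new_seq = st.lik_off ? 0.0 : cd_full_loglik(lc.g, lc.pd, lc.P);
      double new_msc = msc_total(st);
      double lr = (new_seq - old_seq) + (new_msc - old_msc);
      if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
        lc.seqll = new_seq; msc = new_msc; ok = true;
        st.ori_ok[l] = 0;
      } else {
        if (lc.g.ch1[pa] == b) lc.g.ch1[pa] = a; else lc.g.ch2[pa] = a;
        if (lc.g.ch1[pb] == a) lc.g.ch1[pb] = b; else lc.g.ch2[pb] = b;
        lc.g.par[a] = pa; lc.g.par[b] = pb;
        if (!st.lik_off) cd_full_loglik(lc.g, lc.pd, lc.P);
      }
    } else if (mv == 4) {  // species-tree node age, uniform in valid bounds
      int k = st.S.ntip + unif_int(st.S.ntip - 1);
      double lo = 0.0;
      if (st.S.ch1[k] >= 0)
        lo = std::max(st.S.tau[st.S.ch1[k]], st.S.tau[st.S.ch2[k]]);
      double hi = (st.S.par[k] >= 0) ? st.S.tau[st.S.par[k]]
                                      : root_age_bound;
      hi = std::min(hi, min_age_with_origin(st, k));
      if (hi <= lo) continue;
      double old_tau = st.S.tau[k], old_msc = msc, old_yule = yule;
      st.S.tau[k] = lo + R::unif_rand() * (hi - lo);
      double new_msc = msc_total(st);
      double new_yule = cd_yule_logprior(st.S, st.lambda);
      double lr = (new_msc - old_msc) + (new_yule - old_yule);
      if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
        msc = new_msc; yule = new_yule; ok = true;
      } else {
        st.S.tau[k] = old_tau;
      }
    } else if (mv == 5) {  // species-tree NNI with node-age redraw
      int v = st.S.ntip + unif_int(st.S.ntip - 1);
      if (v == st.S.root) continue;
      int w = st.S.par[v];
      int sib = (st.S.ch1[w] == v) ? st.S.ch2[w] : st.S.ch1[w];
      int c = (R::unif_rand() < 0.5) ? st.S.ch1[v] : st.S.ch2[v];
      int other = (st.S.ch1[v] == c) ? st.S.ch2[v] : st.S.ch1[v];
      // reverse-move bounds under the current topology
      double Lr = std::max(st.S.tau[c], st.S.tau[other]);
      double Ur = std::min(st.S.tau[w], min_age_with_origin(st, v));
      if (Ur <= Lr) continue;  // current state unreachable by reverse: skip
      double old_tau = st.S.tau[v], old_msc = msc, old_yule = yule;
      // apply the swap
      if (st.S.ch1[v] == c) st.S.ch1[v] = sib; else st.S.ch2[v] = sib;
      if (st.S.ch1[w] == sib) st.S.ch1[w] = c; else st.S.ch2[w] = c;
      st.S.par[sib] = v; st.S.par[c] = w;
      st.S.rebuild();
      invalidate_origins(st);
      double Lf = std::max(st.S.tau[sib], st.S.tau[other]);
      double Uf = std::min(st.S.tau[w], min_age_with_origin(st, v));
      bool accepted = false;
      if (Uf > Lf) {
        st.S.tau[v] = Lf + R::unif_rand() * (Uf - Lf);
        double new_msc = msc_total(st);
        double new_yule = cd_yule_logprior(st.S, st.lambda);
        double lr = (new_msc - old_msc) + (new_yule - old_yule) +
                    std::log((Uf - Lf) / (Ur - Lr));
        if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
          msc = new_msc; yule = new_yule; accepted = true;
        }
      }
      if (!accepted) {
        st.S.tau[v] = old_tau;
        if (st.S.ch1[v] == sib) st.S.ch1[v] = c; else st.S.ch2[v] = c;
        if (st.S.ch1[w] == c) st.S.ch1[w] = sib; else st.S.ch2[w] = sib;
        st.S.par[sib] = w; st.S.par[c] = v;
        st.S.rebuild();
      }
      invalidate_origins(st);
      ok = accepted;
    } else if (mv == 6) {  // theta multiplier (log-uniform prior cancels)
      int b = unif_int(nsp_nodes);
      double c = std::exp(tun_theta.eps * (R::unif_rand() - 0.5));
      double prop = st.S.theta[b] * c;
      bool accepted = false;
      if (prop >= st.th_lo && prop <= st.th_hi) {
        double old_theta = st.S.theta[b], old_msc = msc;
        st.S.theta[b] = prop;
        double new_msc = msc_total(st);
        if (new_msc != CD_NEG_INF &&
            std::log(R::unif_rand()) < new_msc - old_msc) {
          msc = new_msc; accepted = true;
        } else st.S.theta[b] = old_theta;
      }
      tun_theta.update(accepted, tuning);
      ok = accepted;
    } else if (mv == 7) {
      // lambda Gibbs under f(lambda) = 1/lambda truncated to [lam_lo,
      // lam_hi]; the truncation makes the joint prior proper (see vignette)
      double H = st.S.tau[st.S.root];
      for (int v = st.S.ntip; v < nsp_nodes; ++v) H += st.S.tau[v];
      double shape = st.S.ntip - 1;
      double plo = R::pgamma(LAM_LO, shape, 1.0 / H, 1, 0);
      double phi = R::pgamma(LAM_HI, shape, 1.0 / H, 1, 0);
      double u = plo + R::unif_rand() * (phi - plo);
      u = std::min(std::max(u, 1e-12), 1.0 - 1e-12);
      st.lambda = R::qgamma(u, shape, 1.0 / H, 1, 0);
      st.lambda = std::min(std::max(st.lambda, LAM_LO), LAM_HI);
      yule = cd_yule_logprior(st.S, st.lambda);
      ok = true;
    } else {  // coordinated scale of all ages (and thetas)
      double c = std::exp(tun_scale.eps * (R::unif_rand() - 0.5));
      bool in_bounds = st.S.tau[st.S.root] * c <= root_age_bound;
      for (int b = 0; in_bounds && b < nsp_nodes; ++b) {
        double t = st.S.theta[b] * c;
        if (t < st.th_lo || t > st.th_hi) in_bounds = false;
      }
      bool accepted = false;
      if (in_bounds) {
        int D = st.S.ntip - 1;  // species-tree internal ages
        for (auto &lc : st.loci) D += lc.g.ntip - 1;
        double old_msc = msc, old_yule = yule;
        double old_seq = 0;
        std::vector<double> old_ll((size_t)st.loci.size());
        for (size_t l = 0; l < st.loci.size(); ++l) {
          old_ll[l] = st.loci[l].seqll; old_seq += old_ll[l];
        }
        for (int v = st.S.ntip; v < nsp_nodes; ++v) st.S.tau[v] *= c;
        for (int b = 0; b < nsp_nodes; ++b) st.S.theta[b] *= c;
        for (auto &lc : st.loci)
          for (int v = lc.g.ntip; v < lc.g.nnode; ++v) lc.g.age[v] *= c;
        double new_seq = 0;
        for (auto &lc : st.loci) {
          lc.seqll = st.lik_off ? 0.0 : cd_full_loglik(lc.g, lc.pd, lc.P);
          new_seq += lc.seqll;
        }
        double new_msc = msc_total(st);
        double new_yule = cd_yule_logprior(st.S, st.lambda);
        double lr = (new_seq - old_seq) + (new_msc - old_msc) +
                    (new_yule - old_yule) + D * std::log(c);
        if (new_msc != CD_NEG_INF && std::log(R::unif_rand()) < lr) {
          msc = new_msc; yule = new_yule; accepted = true;
        } else {
          for (int v = st.S.ntip; v < nsp_nodes; ++v) st.S.tau[v] /= c;
          for (int b = 0; b < nsp_nodes; ++b) st.S.theta[b] /= c;
          for (size_t l = 0; l < st.loci.size(); ++l) {
            Locus &lc = st.loci[l];
            for (int v = lc.g.ntip; v < lc.g.nnode; ++v) lc.g.age[v] /= c;
            lc.seqll = old_ll[l];
            if (!st.lik_off) cd_full_loglik(lc.g, lc.pd, lc.P);
          }
        }
      }
      tun_scale.update(accepted, tuning);
      ok = accepted;
    }
    if (ok) acc[mv]++;

    if (iter % sample_every == 0 && nsamp < nsamp_max) {
      for (int v = 0; v < nsp_nodes; ++v) {
        out_par(nsamp, v) = st.S.par[v];
        out_tau(nsamp, v) = st.S.tau[v];
      }
      out_lambda[nsamp] = st.lambda;
      double tot = 0;
      for (auto &lc : st.loci) tot += lc.seqll;
      out_ll[nsamp] = tot + msc + yule;
      nsamp++;
    }
  }

  NumericVector acc_rate(NMOVES);
  for (int i = 0; i < NMOVES; ++i)
    acc_rate[i] = tries[i] > 0 ? (double)acc[i] / tries[i] : NA_REAL;
  List final_genetrees(st.loci.size());
  NumericVector final_seqll(st.loci.size()), fresh_seqll(st.loci.size());
  for (size_t l = 0; l < st.loci.size(); ++l) {
    Locus &lc = st.loci[l];
    final_genetrees[l] = List::create(
        _["par"] = IntegerVector(lc.g.par.begin(), lc.g.par.end()),
        _["age"] = NumericVector(lc.g.age.begin(), lc.g.age.end()));
    final_seqll[l] = lc.seqll;
    fresh_seqll[l] = st.lik_off ? 0.0 : cd_full_loglik(lc.g, lc.pd, lc.P);
  }
  return List::create(
      _["par"] = out_par(Range(0, std::max(nsamp - 1, 0)), _),
      _["tau"] = out_tau(Range(0, std::max(nsamp - 1, 0)), _),
      _["lambda"] = out_lambda[Range(0, std::max(nsamp - 1, 0))],
      _["logpost"] = out_ll[Range(0, std::max(nsamp - 1, 0))],
      _["acc"] = acc_rate,
      _["theta"] = NumericVector(st.S.theta.begin(), st.S.theta.end()),
      _["final_genetrees"] = final_genetrees,
      _["final_seqll"] = final_seqll,
      _["fresh_seqll"] = fresh_seqll);
}
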