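// Core per-locus kernels for the multispecies coalescent machinery:
// JC69 pruning likelihood over site patterns, MSC / MSC-I gene-tree log
// density, backward-in-time gene-tree simulation, and the combined
// per-locus MCMC sweep (independence resimulation + within-epoch node-age
// slides).  The species model is passed as flat arrays prepared by the R
// side:
//   time[v]        event time of species node v (tips 0)
//   parent[v]      primary parent (0 for the root)
//   donor[v]       partner attachment node for hybrid nodes (0 otherwise)
//   phi[v]         donor-path probability at hybrid node v
//   theta_above[v] theta of the population on the branch above v
//   ev_*           merged event list sorted by time: kind 0 = divergence
//                  (node ev_n1), kind 1 = introgression pair (ev_n1, ev_n2)
// Gene trees use nodes 1..n for tips and n+1..2n-1 for coalescences.
// All randomness comes from R's RNG, so seeds set in R reproduce exactly.

#include <Rcpp.h>
#include <array>
using namespace Rcpp;

struct SpeciesModel {
  NumericVector time, phi, theta;
  IntegerVector parent, donor;
  NumericVector ev_time;
  IntegerVector ev_kind, ev_n1, ev_n2;
};

static SpeciesModel unpack_spm(const List &spm) {
  SpeciesModel m;
  m.time = spm["time"]; m.phi = spm["phi"]; m.theta = spm["theta_above"];
  m.parent = spm["parent"]; m.donor = spm["donor"];
  m.ev_time = spm["ev_time"]; m.ev_kind = spm["ev_kind"];
  m.ev_n1 = spm["ev_n1"]; m.ev_n2 = spm["ev_n2"];
  return m;
}

struct Tree {
  std::vector<int> parent;       // 2n-1, 0 = root
  std::vector<double> age;       // 2n-1
  std::vector<int> pop0;         // n
  std::vector<std::array<int, 3>> cross; // (gene node, hyb node, donor flag)
};

static Tree tree_from_list(const List &tr) {
  Tree t;
  IntegerVector p = tr["parent"], q = tr["pop0"];
  NumericVector a = tr["age"];
  IntegerMatrix c = tr["crossings"];
  t.parent.assign(p.begin(), p.end());
  t.age.assign(a.begin(), a.end());
  t.pop0.assign(q.begin(), q.end());
  for (int r = 0; r < c.nrow(); ++r)
    t.cross.push_back({c(r, 0), c(r, 1), c(r, 2)});
  return t;
}

static List tree_to_list(const Tree &t) {
  IntegerMatrix c(t.cross.size(), 3);
  for (size_t r = 0; r < t.cross.size(); ++r) {
    c(r, 0) = t.cross[r][0]; c(r, 1) = t.cross[r][1]; c(r, 2) = t.cross[r][2];
  }
  return List::create(_["parent"] = IntegerVector(t.parent.begin(), t.parent.end()),
                      _["age"] = NumericVector(t.age.begin(), t.age.end()),
                      _["pop0"] = IntegerVector(t.pop0.begin(), t.pop0.end()),
                      _["crossings"] = c);
}

// ---------------------------------------------------------------- pruning

static double pruning_core(const std::vector<int> &parent,
                           const std::vector<double> &age,
                           const double *partials, const double *weights,
                           int P, int n_tip) {
  const int m = (int)parent.size();
  std::vector<std::vector<int>> kids(m + 1);
  int root = 0;
  for (int v = 1; v <= m; ++v) {
    if (parent[v - 1] == 0) root = v; else kids[parent[v - 1]].push_back(v);
  }
  std::vector<int> order; order.reserve(m);
  std::vector<int> stack; stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (int c : kids[v]) stack.push_back(c);
  }
  std::reverse(order.begin(), order.end());
  std::vector<double> L((size_t)m * P * 4);
  std::vector<double> scale(P, 0.0);
  for (int t = 0; t < n_tip; ++t)
    for (int p = 0; p < P; ++p)
      for (int s = 0; s < 4; ++s)
        L[(((size_t)t) * P + p) * 4 + s] = partials[s + 4 * (p + (size_t)P * t)];
  for (int v : order) {
    if (v <= n_tip) continue;
    double *Lv = &L[(((size_t)v - 1) * P) * 4];
    for (int p = 0; p < P; ++p) for (int s = 0; s < 4; ++s) Lv[4 * p + s] = 1.0;
    for (int c : kids[v]) {
      double t = age[v - 1] - age[c - 1];
      if (t < 0) return NA_REAL;
      double e = std::exp(-4.0 * t / 3.0);
      double q = 0.25 - 0.25 * e;
      const double *Lc = &L[(((size_t)c - 1) * P) * 4];
      for (int p = 0; p < P; ++p) {
        double S = Lc[4 * p] + Lc[4 * p + 1] + Lc[4 * p + 2] + Lc[4 * p + 3];
        for (int s = 0; s < 4; ++s)
          Lv[4 * p + s] *= q * S + e * Lc[4 * p + s];
      }
    }
    for (int p = 0; p < P; ++p) {
      double mx = 0.0;
      for (int s = 0; s < 4; ++s) mx = std::max(mx, Lv[4 * p + s]);
      if (mx > 0 && mx < 1e-200) {
        for (int s = 0; s < 4; ++s) Lv[4 * p + s] /= mx;
        scale[p] += std::log(mx);
      } else if (mx == 0) return R_NegInf;
    }
  }
  double ll = 0.0;
  const double *Lr = &L[(((size_t)root - 1) * P) * 4];
  for (int p = 0; p < P; ++p) {
    double s = 0.25 * (Lr[4 * p] + Lr[4 * p + 1] + Lr[4 * p + 2] + Lr[4 * p + 3]);
    if (s <= 0) return R_NegInf;
    ll += weights[p] * (std::log(s) + scale[p]);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_pruning(IntegerVector parent, NumericVector age,
                   NumericVector partials, NumericVector weights, int n_tip) {
  std::vector<int> p(parent.begin(), parent.end());
  std::vector<double> a(age.begin(), age.end());
  return pruning_core(p, a, partials.begin(), weights.begin(),
                      weights.size(), n_tip);
}

// ---------------------------------------------------------------- density

// mode: 0 = strict (missing crossing -> NA), 1 = complete missing crossings
// by drawing Bernoulli(phi); logq accumulates the draw log-probability and
// `used` (if non-null) collects the used crossing set with a drawn flag.
static double density_core(const SpeciesModel &M, const Tree &T, int mode,
                           double *logq,
                           std::vector<std::array<int, 4>> *used,
                           bool &missing,
                           double *crow = nullptr, double *arow = nullptr,
                           double *h1row = nullptr, double *h0row = nullptr) {
  missing = false;
  const int n = (int)T.pop0.size(), m = (int)T.parent.size();
  std::vector<int> pop(m + 1, 0);
  std::vector<char> active(m + 1, 0);
  for (int i = 1; i <= n; ++i) { pop[i] = T.pop0[i - 1]; active[i] = 1; }
  std::vector<int> coal;
  for (int v = n + 1; v <= m; ++v) coal.push_back(v);
  std::sort(coal.begin(), coal.end(), [&](int a, int b) {
    return T.age[a - 1] < T.age[b - 1]; });
  std::vector<std::vector<int>> kids(m + 1);
  for (int v = 1; v <= m; ++v) if (T.parent[v - 1] > 0)
    kids[T.parent[v - 1]].push_back(v);
  const int ns = M.ev_time.size();
  double t = 0.0, logd = 0.0;
  size_t ic = 0; int is = 0, n_active = n;
  auto wait = [&](double t1) {
    if (t1 <= t) return;
    std::vector<int> seen, cnt;
    for (int v = 1; v <= m; ++v) if (active[v]) {
      int p = pop[v]; bool f = false;
      for (size_t j = 0; j < seen.size(); ++j)
        if (seen[j] == p) { cnt[j]++; f = true; break; }
      if (!f) { seen.push_back(p); cnt.push_back(1); }
    }
    double r = 0.0;
    for (size_t j = 0; j < seen.size(); ++j) {
      double kk = (double)cnt[j] * (cnt[j] - 1);
      r += kk / M.theta[seen[j] - 1];
      if (arow) arow[seen[j] - 1] += kk * (t1 - t);
    }
    logd -= r * (t1 - t);
    t = t1;
  };
  while (is < ns || ic < coal.size()) {
    double ts = (is < ns) ? M.ev_time[is] : R_PosInf;
    double tc = (ic < coal.size()) ? T.age[coal[ic] - 1] : R_PosInf;
    if (ts <= tc) {
      wait(ts);
      if (M.ev_kind[is] == 0) {
        int d = M.ev_n1[is];
        for (int v = 1; v <= m; ++v)
          if (active[v] && M.parent[pop[v] - 1] == d) pop[v] = d;
      } else {
        int hA = M.ev_n1[is], hB = M.ev_n2[is];
        for (int v = 1; v <= m; ++v) if (active[v]) {
          int p = pop[v], h = 0;
          if (M.parent[p - 1] == hA) h = hA;
          else if (M.parent[p - 1] == hB) h = hB;
          if (h) {
            int flag = -1, drawn = 0;
            for (const auto &cr : T.cross)
              if (cr[0] == v && cr[1] == h) { flag = cr[2]; break; }
            double ph = M.phi[h - 1];
            if (flag < 0) {
              if (mode == 0) { missing = true; return NA_REAL; }
              flag = (unif_rand() < ph) ? 1 : 0;
              drawn = 1;
              if (logq) *logq += flag ? std::log(ph) : std::log1p(-ph);
            }
            if (used) used->push_back({v, h, flag, drawn});
            if (flag && h1row) h1row[h - 1] += 1;
            if (!flag && h0row) h0row[h - 1] += 1;
            logd += flag ? std::log(ph) : std::log1p(-ph);
            pop[v] = flag ? M.donor[h - 1] : h;
            if (!R_FINITE(logd)) return R_NegInf;
          }
        }
      }
      ++is;
    } else {
      if (!R_FINITE(tc)) break;
      wait(tc);
      int u = coal[ic];
      if (kids[u].size() != 2) return NA_REAL;
      int c1 = kids[u][0], c2 = kids[u][1];
      if (!active[c1] || !active[c2]) return R_NegInf;
      if (pop[c1] != pop[c2]) return R_NegInf;
      int p = pop[c1];
      logd += std::log(2.0 / M.theta[p - 1]);
      if (crow) crow[p - 1] += 1;
      active[c1] = active[c2] = 0; active[u] = 1; pop[u] = p;
      --n_active; ++ic;
    }
  }
  if (n_active != 1) return R_NegInf;
  return logd;
}

// [[Rcpp::export]]
double cpp_gene_density(List spm, IntegerVector g_parent, NumericVector g_age,
                        IntegerVector g_pop0, IntegerMatrix crossings) {
  SpeciesModel M = unpack_spm(spm);
  Tree T;
  T.parent.assign(g_parent.begin(), g_parent.end());
  T.age.assign(g_age.begin(), g_age.end());
  T.pop0.assign(g_pop0.begin(), g_pop0.end());
  for (int r = 0; r < crossings.nrow(); ++r)
    T.cross.push_back({crossings(r, 0), crossings(r, 1), crossings(r, 2)});
  bool missing;
  double d = density_core(M, T, 0, nullptr, nullptr, missing);
  return missing ? NA_REAL : d;
}

// [[Rcpp::export]]
List cpp_density_complete(List spm, IntegerVector g_parent, NumericVector g_age,
                          IntegerVector g_pop0, IntegerMatrix crossings) {
  SpeciesModel M = unpack_spm(spm);
  Tree T;
  T.parent.assign(g_parent.begin(), g_parent.end());
  T.age.assign(g_age.begin(), g_age.end());
  T.pop0.assign(g_pop0.begin(), g_pop0.end());
  for (int r = 0; r < crossings.nrow(); ++r)
    T.cross.push_back({crossings(r, 0), crossings(r, 1), crossings(r, 2)});
  double logq = 0;
  std::vector<std::array<int, 4>> used;
  bool missing;
  double d = density_core(M, T, 1, &logq, &used, missing);
  IntegerMatrix u(used.size(), 4);
  for (size_t r = 0; r < used.size(); ++r)
    for (int c = 0; c < 4; ++c) u(r, c) = used[r][c];
  return List::create(_["logdens"] = R_FINITE(d) ? d : R_NegInf,
                      _["used"] = u, _["logq"] = logq);
}

// [[Rcpp::export]]
NumericVector cpp_density_many(List spm, List trees) {
  SpeciesModel M = unpack_spm(spm);
  const int L = trees.size();
  NumericVector out(L);
  for (int i = 0; i < L; ++i) {
    Tree T = tree_from_list(trees[i]);
    bool missing;
    double d = density_core(M, T, 0, nullptr, nullptr, missing);
    out[i] = missing ? NA_REAL : d;
  }
  return out;
}

// ------------------------------------------------------------- simulation

static Tree sim_core(const SpeciesModel &M, const std::vector<int> &pop0) {
  const int n = (int)pop0.size(), m = 2 * n - 1;
  Tree T;
  T.parent.assign(m, 0);
  T.age.assign(m, 0.0);
  T.pop0 = pop0;
  std::vector<int> pop(m + 1, 0);
  std::vector<int> act;
  for (int i = 1; i <= n; ++i) { pop[i] = pop0[i - 1]; act.push_back(i); }
  int nxt = n + 1;
  double t = 0.0;
  const int ns = M.ev_time.size();
  int is = 0;
  std::vector<int> seen, cnt;
  std::vector<double> rate;
  while ((int)act.size() > 1 || is < ns) {
    seen.clear(); cnt.clear(); rate.clear();
    for (int v : act) {
      int p = pop[v]; bool f = false;
      for (size_t j = 0; j < seen.size(); ++j)
        if (seen[j] == p) { cnt[j]++; f = true; break; }
      if (!f) { seen.push_back(p); cnt.push_back(1); }
    }
    double R = 0.0;
    for (size_t j = 0; j < seen.size(); ++j) {
      double r = (double)cnt[j] * (cnt[j] - 1) / M.theta[seen[j] - 1];
      rate.push_back(r); R += r;
    }
    double ts = (is < ns) ? M.ev_time[is] : R_PosInf;
    double tc = (R > 0) ? t + exp_rand() / R : R_PosInf;
    if (tc < ts) {
      t = tc;
      double u = unif_rand() * R, accum = 0.0; size_t j = 0;
      for (; j < seen.size(); ++j) { accum += rate[j]; if (u <= accum) break; }
      if (j >= seen.size()) j = seen.size() - 1;
      int p = seen[j];
      std::vector<int> inpop;
      for (int v : act) if (pop[v] == p) inpop.push_back(v);
      int i1 = (int)(unif_rand() * inpop.size());
      if (i1 >= (int)inpop.size()) i1 = 0;
      int i2 = (int)(unif_rand() * (inpop.size() - 1));
      if (i2 >= (int)inpop.size() - 1) i2 = 0;
      if (i2 >= i1) i2++;
      int c1 = inpop[i1], c2 = inpop[i2];
      int u2 = nxt++;
      T.parent[c1 - 1] = u2; T.parent[c2 - 1] = u2; T.age[u2 - 1] = t;
      pop[u2] = p;
      act.erase(std::remove(act.begin(), act.end(), c1), act.end());
      act.erase(std::remove(act.begin(), act.end(), c2), act.end());
      act.push_back(u2);
    } else {
      if (!R_FINITE(ts)) break;
      t = ts;
      if (M.ev_kind[is] == 0) {
        int d = M.ev_n1[is];
        for (int v : act) if (M.parent[pop[v] - 1] == d) pop[v] = d;
      } else {
        int hA = M.ev_n1[is], hB = M.ev_n2[is];
        for (int v : act) {
          int p = pop[v], h = 0;
          if (M.parent[p - 1] == hA) h = hA;
          else if (M.parent[p - 1] == hB) h = hB;
          if (h) {
            int flag = (unif_rand() < M.phi[h - 1]) ? 1 : 0;
            T.cross.push_back({v, h, flag});
            pop[v] = flag ? M.donor[h - 1] : h;
          }
        }
      }
      ++is;
    }
  }
  return T;
}

// [[Rcpp::export]]
List cpp_sim_gene_tree(List spm, IntegerVector g_pop0) {
  SpeciesModel M = unpack_spm(spm);
  std::vector<int> p0(g_pop0.begin(), g_pop0.end());
  return tree_to_list(sim_core(M, p0));
}

// Per-locus coalescent sufficient statistics given the current gene trees:
// C[l,v] = coalescences in population v; A[l,v] = sum of k(k-1)*dt waiting
// terms; H1/H0[l,v] = donor / ancestral crossings at hybrid node v.  The
// gene-tree log density of locus l is
//   sum_v C[l,v] log(2/theta_v) - A[l,v]/theta_v
//   + sum_h H1[l,h] log(phi_h) + H0[l,h] log(1-phi_h),
// which makes theta and phi updates O(1) in the number of loci re-sweeps.
// [[Rcpp::export]]
List cpp_coal_stats(List spm, List trees) {
  SpeciesModel M = unpack_spm(spm);
  const int L = trees.size(), n_sp = M.time.size();
  NumericMatrix C(L, n_sp), A(L, n_sp), H1(L, n_sp), H0(L, n_sp);
  bool missing;
  std::vector<double> cr(n_sp), ar(n_sp), h1(n_sp), h0(n_sp);
  for (int i = 0; i < L; ++i) {
    std::fill(cr.begin(), cr.end(), 0.0);
    std::fill(ar.begin(), ar.end(), 0.0);
    std::fill(h1.begin(), h1.end(), 0.0);
    std::fill(h0.begin(), h0.end(), 0.0);
    Tree T = tree_from_list(trees[i]);
    density_core(M, T, 0, nullptr, nullptr, missing,
                 cr.data(), ar.data(), h1.data(), h0.data());
    for (int v = 0; v < n_sp; ++v) {
      C(i, v) = cr[v]; A(i, v) = ar[v]; H1(i, v) = h1[v]; H0(i, v) = h0[v];
    }
  }
  return List::create(_["C"] = C, _["A"] = A, _["H1"] = H1, _["H0"] = H0);
}

// --------------------------------------------------- combined locus sweep

// One MCMC sweep over all loci: an independence resimulation proposal
// (accepted on the tempered likelihood ratio) and one within-epoch
// node-age slide per locus.  Updates trees / ll / ld in place (returned).
// [[Rcpp::export]]
List cpp_locus_sweep(List spm, List trees, List partials, List weights,
                     IntegerVector n_seq, NumericVector ll, NumericVector ld,
                     double beta, double step_age) {
  SpeciesModel M = unpack_spm(spm);
  const int L = trees.size();
  NumericVector ll2(clone(ll)), ld2(clone(ld));
  int acc_resim = 0, acc_age = 0, prop_mult = 0, acc_mult = 0;
  List out_trees(L);
  bool missing;
  for (int i = 0; i < L; ++i) {
    Tree T = tree_from_list(trees[i]);
    NumericVector part = partials[i], w = weights[i];
    const int n = n_seq[i], P = w.size();
    // --- independence resimulation
    Tree Tp = sim_core(M, T.pop0);
    double llp = pruning_core(Tp.parent, Tp.age, part.begin(), w.begin(), P, n);
    if (R_FINITE(llp) &&
        std::log(unif_rand()) < beta * (llp - ll2[i])) {
      double dd = density_core(M, Tp, 0, nullptr, nullptr, missing);
      T = Tp; ll2[i] = llp; ld2[i] = dd; ++acc_resim;
    }
    // --- within-epoch age slide on one internal node
    int j = n + 1 + (int)(unif_rand() * (n - 1));
    if (j > 2 * n - 1) j = 2 * n - 1;
    double a0 = T.age[j - 1];
    double lo = 0.0, hi = R_PosInf;
    for (int v = 1; v <= 2 * n - 1; ++v)
      if (T.parent[v - 1] == j) lo = std::max(lo, T.age[v - 1]);
    if (T.parent[j - 1] > 0) hi = T.age[T.parent[j - 1] - 1];
    for (int e = 0; e < M.ev_time.size(); ++e) {
      double te = M.ev_time[e];
      if (te <= a0) lo = std::max(lo, te);
      else hi = std::min(hi, te);
    }
    if (hi > lo) {
      double a2, lhr = 0.0;
      bool mult = !R_FINITE(hi);
      if (!mult) a2 = lo + unif_rand() * (hi - lo);
      else {
        a2 = lo + (a0 - lo) * std::exp(step_age * (unif_rand() - 0.5));
        lhr = std::log(a2 - lo) - std::log(a0 - lo);
        ++prop_mult;
      }
      Tree Tp2 = T;
      Tp2.age[j - 1] = a2;
      double dd = density_core(M, Tp2, 0, nullptr, nullptr, missing);
      if (R_FINITE(dd) && !missing) {
        double llp2 = pruning_core(Tp2.parent, Tp2.age, part.begin(),
                                   w.begin(), P, n);
        double a = (dd - ld2[i]) + beta * (llp2 - ll2[i]) + lhr;
        if (std::log(unif_rand()) < a) {
          T = Tp2; ld2[i] = dd; ll2[i] = llp2;
          ++acc_age;
          if (mult) ++acc_mult;
        }
      }
    }
    // --- hybrid-path indicator flip (density-only Metropolis step)
    if (!T.cross.empty()) {
      int r = (int)(unif_rand() * T.cross.size());
      if (r >= (int)T.cross.size()) r = 0;
      Tree Tp3 = T;
      Tp3.cross[r][2] = 1 - Tp3.cross[r][2];
      double dd = density_core(M, Tp3, 0, nullptr, nullptr, missing);
      if (R_FINITE(dd) && !missing &&
          std::log(unif_rand()) < dd - ld2[i]) {
        T = Tp3; ld2[i] = dd;
      }
    }
    out_trees[i] = tree_to_list(T);
  }
  return List::create(_["trees"] = out_trees, _["ll"] = ll2, _["ld"] = ld2,
                      _["acc_resim"] = acc_resim, _["acc_age"] = acc_age,
                      _["prop_mult"] = prop_mult, _["acc_mult"] = acc_mult);
}

// Log-likelihood of every locus given its current gene tree (used by the
// whole-model scaling move).
// [[Rcpp::export]]
NumericVector cpp_pruning_many(List trees, List partials, List weights,
                               IntegerVector n_seq, double scale_ages) {
  const int L = trees.size();
  NumericVector out(L);
  for (int i = 0; i < L; ++i) {
    Tree T = tree_from_list(trees[i]);
    if (scale_ages != 1.0)
      for (auto &a : T.age) a *= scale_ages;
    NumericVector part = partials[i], w = weights[i];
    out[i] = pruning_core(T.parent, T.age, part.begin(), w.begin(),
                          w.size(), n_seq[i]);
  }
  return out;
}

// ------------------------------------------------ triplet IM likelihood

// Per-locus log-sum-exp over genealogy quadrature atoms: locus l with
// configuration cfg[l] contributes
//   log sum_g exp( logW(g, cfg[l]) + sum_c n[l,c] * logp[g,c] ).
// [[Rcpp::export]]
double cpp_triplet_loglik(NumericMatrix counts, IntegerVector cfg,
                          NumericVector mult,
                          NumericMatrix logp, NumericMatrix logW) {
  const int L = counts.nrow(), G = logp.nrow();
  double total = 0.0;
  std::vector<double> s(G);
  for (int l = 0; l < L; ++l) {
    const int k = cfg[l] - 1;
    const double n1 = counts(l, 0), n2 = counts(l, 1), n3 = counts(l, 2),
                 n4 = counts(l, 3), n5 = counts(l, 4);
    double mx = R_NegInf;
    for (int g = 0; g < G; ++g) {
      double v = logW(g, k) + n1 * logp(g, 0) + n2 * logp(g, 1) +
                 n3 * logp(g, 2) + n4 * logp(g, 3) + n5 * logp(g, 4);
      s[g] = v;
      if (v > mx) mx = v;
    }
    if (!R_FINITE(mx)) return R_NegInf;
    double acc = 0.0;
    for (int g = 0; g < G; ++g) acc += std::exp(s[g] - mx);
    total += mult[l] * (mx + std::log(acc));
  }
  return total;
}
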