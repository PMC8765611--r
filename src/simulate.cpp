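// Desk-scale chromosome simulator.
//
// Neutral recombining chromosomes are generated with a sequential Markov
// coalescent (SMC'): the marginal genealogy at every position is an exact
// coalescent tree, so the site-frequency spectrum and Watterson's expectation
// hold by construction; linkage along the chromosome follows the SMC'
// approximation to the full ancestral recombination graph.
//
// Selective sweeps are generated forward in time: the whole population
// (2N haploid sequences) is drawn from the neutral generator, a single
// beneficial mutation is injected, and discrete Wright-Fisher generations
// with selection, crossover and new mutation are run until the beneficial
// allele reaches the requested population frequency (rejection sampling over
// trajectories) or has been fixed for the requested number of generations.
//
// All randomness comes from R's RNG (reproducible under set.seed()).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// SMC' tree

struct SmcTree {
  int n;                      // leaves
  std::vector<double> time;   // node times (coalescent units of 2N gens)
  std::vector<int> par, ch1, ch2;
  int root;
  double ttot;
  std::vector<double> itimes;  // sorted internal node times

  void recompute_ttot() {
    ttot = 0.0;
    int nn = 2 * n - 1;
    for (int v = 0; v < nn; ++v)
      if (v != root) ttot += time[par[v]] - time[v];
  }

  // a coalescence moved from told to tnew: keep the sorted time index in
  // step and recompute the total length (the root carries no stem branch,
  // so no constant-time increment is valid in general)
  void move_itime(double told, double tnew) {
    std::vector<double>::iterator it =
        std::lower_bound(itimes.begin(), itimes.end(), told);
    itimes.erase(it);
    itimes.insert(std::lower_bound(itimes.begin(), itimes.end(), tnew), tnew);
    recompute_ttot();
  }
};

static SmcTree init_coalescent(int n) {
  SmcTree T;
  T.n = n;
  int nn = 2 * n - 1;
  T.time.assign(nn, 0.0);
  T.par.assign(nn, -1);
  T.ch1.assign(nn, -1);
  T.ch2.assign(nn, -1);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int next = n;
  int k = n;
  while (k > 1) {
    t += 2.0 * R::exp_rand() / ((double)k * (k - 1));
    int i = (int)(R::unif_rand() * k);
    int j = (int)(R::unif_rand() * (k - 1));
    if (j >= i) j++;
    int a = active[i], b = active[j];
    T.time[next] = t;
    T.ch1[next] = a;
    T.ch2[next] = b;
    T.par[a] = next;
    T.par[b] = next;
    // remove the two, add the parent
    if (i > j) std::swap(i, j);
    active[i] = next;
    active[j] = active[k - 1];
    active.pop_back();
    next++;
    k--;
  }
  T.root = next - 1;
  T.recompute_ttot();
  T.itimes.assign(T.time.begin() + n, T.time.end());  // ascending by design
  return T;
}

// pick a uniform point on the branches; returns node b and time t_r on b's
// parent branch
static void pick_branch_point(const SmcTree& T, int& b, double& t_r) {
  double u = R::unif_rand() * T.ttot;
  int nn = 2 * T.n - 1;
  double cum = 0.0;
  b = -1;
  for (int v = 0; v < nn; ++v) {
    if (v == T.root) continue;
    double len = T.time[T.par[v]] - T.time[v];
    if (u < cum + len) {
      b = v;
      t_r = T.time[v] + (u - cum);
      return;
    }
    cum += len;
  }
  // numeric fallback: last non-root branch
  for (int v = nn - 1; v >= 0; --v)
    if (v != T.root) { b = v; t_r = T.time[v] + 0.5 * (T.time[T.par[v]] - T.time[v]); return; }
}

// one SMC' transition at a recombination breakpoint
static void smc_update(SmcTree& T) {
  int b; double t_r;
  pick_branch_point(T, b, t_r);

  const std::vector<double>& it = T.itimes;
  int nn = 2 * T.n - 1;

  // simulate re-coalescence from t_r; lineage count k(t) = n - #{it <= t}
  int j = (int)(std::upper_bound(it.begin(), it.end(), t_r) - it.begin());
  int k = T.n - j;
  double t = t_r, t_c;
  while (true) {
    double nxt = (j < (int)it.size()) ? it[j] : R_PosInf;
    double e = R::exp_rand() / (double)k;
    if (t + e < nxt) { t_c = t + e; break; }
    t = nxt;
    j++;
    k--;
    if (k < 1) k = 1;  // above the root only the stem remains
  }

  // partner branch spanning t_c (or the stem above the root)
  int cnt = 0;
  for (int v = 0; v < nn; ++v) {
    if (v == T.root) continue;
    if (T.time[v] <= t_c && t_c < T.time[T.par[v]]) cnt++;
  }
  int partner = -1;  // -1 = stem above root
  if (cnt > 0) {
    int pick = (int)(R::unif_rand() * cnt);
    int seen = 0;
    for (int v = 0; v < nn; ++v) {
      if (v == T.root) continue;
      if (T.time[v] <= t_c && t_c < T.time[T.par[v]]) {
        if (seen == pick) { partner = v; break; }
        seen++;
      }
    }
  }

  if (partner == b) return;  // back-coalescence onto its own branch: invisible

  // restructure: splice parent p out, then re-insert it at t_c
  int p = T.par[b];
  double old_tp = T.time[p];
  int c = (T.ch1[p] == b) ? T.ch2[p] : T.ch1[p];
  int g = T.par[p];
  if (g >= 0) {
    if (T.ch1[g] == p) T.ch1[g] = c; else T.ch2[g] = c;
    T.par[c] = g;
  } else {
    T.root = c;
    T.par[c] = -1;
  }
  int v = partner;
  if (v == p) v = c;  // p's own branch merged into c's on splice

  if (v < 0 || (T.par[v] < 0 && t_c >= T.time[v])) {
    // coalesce with the stem above the (possibly new) root
    int r = T.root;
    T.time[p] = t_c;
    T.ch1[p] = b;
    T.ch2[p] = r;
    T.par[b] = p;
    T.par[r] = p;
    T.par[p] = -1;
    T.root = p;
  } else {
    int gp = T.par[v];
    T.time[p] = t_c;
    T.ch1[p] = b;
    T.ch2[p] = v;
    T.par[b] = p;
    T.par[v] = p;
    T.par[p] = gp;
    if (gp >= 0) {
      if (T.ch1[gp] == v) T.ch1[gp] = p; else T.ch2[gp] = p;
    } else {
      T.root = p;
    }
  }
  T.move_itime(old_tp, t_c);
}

static void leaves_under(const SmcTree& T, int v, std::vector<int>& out) {
  out.clear();
  std::vector<int> stack;
  stack.push_back(v);
  while (!stack.empty()) {
    int w = stack.back();
    stack.pop_back();
    if (w < T.n) { out.push_back(w); continue; }
    stack.push_back(T.ch1[w]);
    stack.push_back(T.ch2[w]);
  }
}

struct MutationSet {
  std::vector<double> pos;
  std::vector<std::vector<int> > carriers;
};

// neutral chromosome of length L for a sample of n sequences;
// theta and rho are the population-scaled totals (4 N mu L, 4 N r L)
static MutationSet smc_simulate(int n, double L, double theta, double rho) {
  SmcTree T = init_coalescent(n);
  MutationSet ms;
  std::vector<int> leaves;
  double x = 0.0;
  while (true) {
    double dx = (rho > 0.0) ? R::exp_rand() / (T.ttot * rho / (2.0 * L)) : R_PosInf;
    double x1 = std::min(x + dx, L);
    // mutations on the segment [x, x1) under the current tree
    double lam = T.ttot * theta / (2.0 * L) * (x1 - x);
    int nm = (lam > 0.0) ? (int)R::rpois(lam) : 0;
    for (int m = 0; m < nm; ++m) {
      double mp = x + R::unif_rand() * (x1 - x);
      int b; double tr;
      pick_branch_point(T, b, tr);
      leaves_under(T, b, leaves);
      ms.pos.push_back(mp);
      ms.carriers.push_back(leaves);
    }
    if (x1 >= L) break;
    x = x1;
    smc_update(T);
  }
  return ms;
}

// order mutations by position and build a markers x n 0/1 matrix
static List mutations_to_matrix(const MutationSet& ms, int n) {
  int S = (int)ms.pos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return ms.pos[a] < ms.pos[b]; });
  NumericVector pos(S);
  IntegerMatrix A(S, n);
  for (int r = 0; r < S; ++r) {
    int i = ord[r];
    pos[r] = ms.pos[i];
    for (size_t c = 0; c < ms.carriers[i].size(); ++c) A(r, ms.carriers[i][c]) = 1;
  }
  return List::create(_["pos"] = pos, _["mat"] = A);
}

// [[Rcpp::export]]
List cpp_sim_neutral(int n, double L, double theta, double rho) {
  MutationSet ms = smc_simulate(n, L, theta, rho);
  return mutations_to_matrix(ms, n);
}

// ---------------------------------------------------------------------------
// forward Wright-Fisher

typedef std::vector<std::vector<double> > Pop;  // sorted mutation positions

static bool has_pos(const std::vector<double>& chrom, double p) {
  return std::binary_search(chrom.begin(), chrom.end(), p);
}

// gamete from the two chromosomes of one parent individual
static void make_gamete(const std::vector<double>& c1,
                        const std::vector<double>& c2, double rL, double muL,
                        double L, std::vector<double>& out) {
  out.clear();
  int ncx = (int)R::rpois(rL);
  if (ncx == 0) {
    out = (R::unif_rand() < 0.5) ? c1 : c2;
  } else {
    std::vector<double> bp(ncx);
    for (int i = 0; i < ncx; ++i) bp[i] = R::unif_rand() * L;
    std::sort(bp.begin(), bp.end());
    bp.push_back(L);
    bool use1 = R::unif_rand() < 0.5;
    double lo = 0.0;
    for (size_t i = 0; i < bp.size(); ++i) {
      const std::vector<double>& src = use1 ? c1 : c2;
      std::vector<double>::const_iterator a =
          std::lower_bound(src.begin(), src.end(), lo);
      std::vector<double>::const_iterator b =
          std::lower_bound(src.begin(), src.end(), bp[i]);
      out.insert(out.end(), a, b);
      lo = bp[i];
      use1 = !use1;
    }
  }
  int nm = (int)R::rpois(muL);
  for (int i = 0; i < nm; ++i) {
    double p = R::unif_rand() * L;
    out.insert(std::lower_bound(out.begin(), out.end(), p), p);
  }
}

// one Wright-Fisher generation; fitness 1, 1+hs, 1+s by count of the
// beneficial allele (s = 0 for neutral drift)
static void wf_next(const Pop& pop, Pop& nxt, double muL, double rL, double L,
                    double s, double h, double pos_sel) {
  int twoN = (int)pop.size();
  int N = twoN / 2;
  std::vector<double> cw(N);
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (s != 0.0) {
      int g = (has_pos(pop[2 * i], pos_sel) ? 1 : 0) +
              (has_pos(pop[2 * i + 1], pos_sel) ? 1 : 0);
      w = (g == 0) ? 1.0 : ((g == 1) ? 1.0 + h * s : 1.0 + s);
    }
    tot += w;
    cw[i] = tot;
  }
  nxt.resize(twoN);
  for (int j = 0; j < twoN; ++j) {
    int parent;
    if (s != 0.0) {
      double u = R::unif_rand() * tot;
      parent = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      if (parent >= N) parent = N - 1;
    } else {
      parent = (int)(R::unif_rand() * N);
    }
    make_gamete(pop[2 * parent], pop[2 * parent + 1], rL, muL, L, nxt[j]);
  }
}

static double sel_freq(const Pop& pop, double pos_sel) {
  int c = 0;
  for (size_t i = 0; i < pop.size(); ++i)
    if (has_pos(pop[i], pos_sel)) c++;
  return (double)c / pop.size();
}

// sample n sequences = n/2 random individuals (both chromosomes each)
static std::vector<int> sample_individuals(int N, int n_ind) {
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_ind; ++i) {
    int j = i + (int)(R::unif_rand() * (N - i));
    std::swap(idx[i], idx[j]);
  }
  idx.resize(n_ind);
  return idx;
}

// site matrix of a set of sampled chromosomes; drops sites that are not
// segregating in the sample
static List sample_to_matrix(const Pop& pop, const std::vector<int>& inds,
                             double pos_sel) {
  std::vector<int> chroms;
  for (size_t i = 0; i < inds.size(); ++i) {
    chroms.push_back(2 * inds[i]);
    chroms.push_back(2 * inds[i] + 1);
  }
  int n = (int)chroms.size();
  std::vector<double> all;
  for (int i = 0; i < n; ++i)
    all.insert(all.end(), pop[chroms[i]].begin(), pop[chroms[i]].end());
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end()), all.end());
  int S = (int)all.size();
  std::vector<int> count(S, 0);
  for (int i = 0; i < n; ++i) {
    const std::vector<double>& c = pop[chroms[i]];
    for (size_t m = 0; m < c.size(); ++m) {
      int k = (int)(std::lower_bound(all.begin(), all.end(), c[m]) - all.begin());
      count[k]++;
    }
  }
  int nsel = 0;
  if (!ISNA(pos_sel)) {
    for (int i = 0; i < n; ++i)
      if (has_pos(pop[chroms[i]], pos_sel)) nsel++;
  }
  std::vector<int> keep;
  for (int k = 0; k < S; ++k)
    if (count[k] > 0 && count[k] < n) keep.push_back(k);
  NumericVector pos(keep.size());
  IntegerMatrix A((int)keep.size(), n);
  for (size_t r = 0; r < keep.size(); ++r) pos[r] = all[keep[r]];
  for (int i = 0; i < n; ++i) {
    const std::vector<double>& c = pop[chroms[i]];
    for (size_t r = 0; r < keep.size(); ++r)
      if (std::binary_search(c.begin(), c.end(), all[keep[r]])) A((int)r, i) = 1;
  }
  return List::create(_["pos"] = pos, _["mat"] = A,
                      _["sample_freq"] = (double)nsel / n);
}

// [[Rcpp::export]]
List cpp_sim_sweep(int twoN, double L, double theta, double rho, double muL,
                   double rL, int n_sample, double s, double h, double pos_sel,
                   double target, double tol, int fixed_extra_gens,
                   int max_attempts, int max_gens) {
  if (n_sample % 2 != 0) stop("sample size must be even");
  MutationSet ms = smc_simulate(twoN, L, theta, rho);
  Pop init((size_t)twoN);
  for (size_t m = 0; m < ms.pos.size(); ++m)
    for (size_t c = 0; c < ms.carriers[m].size(); ++c)
      init[ms.carriers[m][c]].push_back(ms.pos[m]);
  for (int i = 0; i < twoN; ++i) std::sort(init[i].begin(), init[i].end());

  Pop pop, nxt;
  bool fixed_mode = fixed_extra_gens >= 0;
  int attempts = 0;
  for (attempts = 1; attempts <= max_attempts; ++attempts) {
    pop = init;
    int carrier = (int)(R::unif_rand() * twoN);
    pop[carrier].insert(
        std::lower_bound(pop[carrier].begin(), pop[carrier].end(), pos_sel),
        pos_sel);
    bool ok = false, failed = false;
    double freq = 1.0 / twoN;
    for (int g = 0; g < max_gens; ++g) {
      wf_next(pop, nxt, muL, rL, L, s, h, pos_sel);
      pop.swap(nxt);
      freq = sel_freq(pop, pos_sel);
      if (freq == 0.0) { failed = true; break; }
      if (fixed_mode) {
        if (freq == 1.0) {
          for (int e = 0; e < fixed_extra_gens; ++e) {
            wf_next(pop, nxt, muL, rL, L, 0.0, h, pos_sel);
            pop.swap(nxt);
          }
          ok = true;
          break;
        }
      } else {
        if (std::fabs(freq - target) <= tol + 1e-12) { ok = true; break; }
        if (freq > target + tol) { failed = true; break; }
      }
    }
    if (ok) {
      std::vector<int> inds = sample_individuals(twoN / 2, n_sample / 2);
      List out = sample_to_matrix(pop, inds, pos_sel);
      out["pop_freq"] = fixed_mode ? 1.0 : freq;
      out["attempts"] = attempts;
      return out;
    }
    (void)failed;  // unresolved trajectories count as failed attempts
  }
  stop("sweep trajectory conditioning failed after %d attempts", max_attempts);
}

// [[Rcpp::export]]
List cpp_sim_split(int twoN, double L, double theta, double rho, double muL,
                   double rL, int n_sample, int split_gens) {
  if (n_sample % 2 != 0) stop("sample size must be even");
  MutationSet ms = smc_simulate(twoN, L, theta, rho);
  Pop anc((size_t)twoN);
  for (size_t m = 0; m < ms.pos.size(); ++m)
    for (size_t c = 0; c < ms.carriers[m].size(); ++c)
      anc[ms.carriers[m][c]].push_back(ms.pos[m]);
  for (int i = 0; i < twoN; ++i) std::sort(anc[i].begin(), anc[i].end());

  List out(2);
  for (int p = 0; p < 2; ++p) {
    Pop pop = anc, nxt;
    for (int g = 0; g < split_gens; ++g) {
      wf_next(pop, nxt, muL, rL, L, 0.0, 1.0, NA_REAL);
      pop.swap(nxt);
    }
    std::vector<int> inds = sample_individuals(twoN / 2, n_sample / 2);
    out[p] = sample_to_matrix(pop, inds, NA_REAL);
  }
  return List::create(_["pop1"] = out[0], _["pop2"] = out[1]);
}

// internal diagnostic: run `updates` SMC' transitions and report the
// incrementally tracked total branch length, a from-scratch recomputation,
// and the tree height
// [[Rcpp::export]]
NumericVector cpp_smc_debug(int n, int updates) {
  SmcTree T = init_coalescent(n);
  for (int i = 0; i < updates; ++i) smc_update(T);
  double inc = T.ttot;
  T.recompute_ttot();
  return NumericVector::create(inc, T.ttot, T.time[T.root]);
}
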