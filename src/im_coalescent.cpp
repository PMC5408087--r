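// Structured-coalescent engine for the two-population isolation-with-migration
// (IM) model. Time runs backwards in generations; population sizes are diploid
// (a pair of lineages in a population of size N coalesces at rate 1/(2N) per
// generation). Migration rates are the *forward* per-generation rates; under
// time reversal a lineage currently in A finds its parent in P at rate mPA
// (the fraction of A replaced by P migrants each generation), and vice versa.
//
// Two simulation modes:
//  * exact: Gillespie simulation of every coalescence and migration event.
//  * strong-migration collapse: once the per-lineage location chain
//    (relaxation rate mPA+mAP) is much faster than any per-pair coalescence
//    rate AND has had time to relax from the sampling configuration, lineage
//    locations are treated as i.i.d. stationary and pairs coalesce at the
//    location-averaged rate piA^2/(2NA) + piP^2/(2NP). This removes the
//    per-migration-event cost, which is prohibitive when N*m is large.
// The collapse is only entered when (mPA+mAP) > strongFactor / (2*min(N)), or
// as a guarded fallback after maxExactEvents exact events (extreme corners of
// parameter space). strongFactor = Inf forces the exact path.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  int n;                        // number of sampled lineages
  std::vector<int> child1, child2;   // per internal node (size n-1), 0-based ids
  std::vector<double> itime;         // internal node times (increasing)
  std::vector<int> leafPop;          // 0 = A, 1 = P
};

struct Ctrl {
  double strongFactor;   // collapse when relax > strongFactor/(2*minN)
  double relaxTime;      // exact burn-in, units of 1/relax, before collapse
  double maxExactEvents; // fallback cap on exact events per genealogy
};

inline int pick(const int k) { return (int)(unif_rand() * k) % k; }

// simulate one genealogy; fills tr
void sim_tree(double nAnc, double nA, double nP, double tDiv,
              double mPA, double mAP, int sampA, int sampP,
              const Ctrl& ctl, Tree& tr) {
  const int n = sampA + sampP;
  tr.n = n;
  tr.child1.assign(n - 1, -1);
  tr.child2.assign(n - 1, -1);
  tr.itime.assign(n - 1, 0.0);
  tr.leafPop.assign(n, 0);
  for (int i = sampA; i < n; ++i) tr.leafPop[i] = 1;

  std::vector<int> inA, inP, act;
  inA.reserve(n); inP.reserve(n); act.reserve(n);
  for (int i = 0; i < sampA; ++i) inA.push_back(i);
  for (int i = sampA; i < n; ++i) inP.push_back(i);

  double t = 0.0;
  int made = 0;                  // internal nodes created
  int nextId = n;
  const double relax = mPA + mAP;
  const double minN = std::min(nA, nP);
  const bool strongOK = relax > 0 && relax > ctl.strongFactor * 0.5 / minN;
  const double relaxUntil = strongOK ? ctl.relaxTime / relax : R_PosInf;
  double events = 0.0;
  bool collapsed = false;

  // phase 1: two populations, t < tDiv
  while (made < n - 1 && t < tDiv) {
    if (!collapsed && relax > 0 &&
        ((strongOK && t >= relaxUntil) || events > ctl.maxExactEvents)) {
      collapsed = true;
      act.clear();
      act.insert(act.end(), inA.begin(), inA.end());
      act.insert(act.end(), inP.begin(), inP.end());
    }
    if (!collapsed) {
      const int kA = (int)inA.size(), kP = (int)inP.size();
      const double cA = kA * (kA - 1) / 2.0 / (2.0 * nA);
      const double cP = kP * (kP - 1) / 2.0 / (2.0 * nP);
      const double gA = kA * mPA, gP = kP * mAP;
      const double tot = cA + cP + gA + gP;
      if (tot <= 0.0) {
        if (!R_FINITE(tDiv))
          stop("lineages in separate populations with no migration and infinite divergence time can never coalesce");
        t = tDiv; break;
      }
      const double dt = exp_rand() / tot;
      if (t + dt >= tDiv) { t = tDiv; break; }
      t += dt; events += 1.0;
      double u = unif_rand() * tot;
      if (u < cA || u < cA + cP) {
        std::vector<int>& pop = (u < cA) ? inA : inP;
        const int k = (int)pop.size();
        int i = pick(k); int j = pick(k - 1); if (j >= i) ++j;
        const int a = pop[i], b = pop[j];
        tr.child1[made] = a; tr.child2[made] = b; tr.itime[made] = t;
        if (i > j) std::swap(i, j);
        pop[i] = nextId; pop.erase(pop.begin() + j);
        ++nextId; ++made;
      } else if (u < cA + cP + gA) {          // migration A -> P (backwards)
        const int i = pick((int)inA.size());
        inP.push_back(inA[i]); inA.erase(inA.begin() + i);
      } else {                                 // migration P -> A
        const int i = pick((int)inP.size());
        inA.push_back(inP[i]); inP.erase(inP.begin() + i);
      }
    } else {
      const int k = (int)act.size();
      const double piA = mAP / relax, piP = mPA / relax;
      const double reff = piA * piA / (2.0 * nA) + piP * piP / (2.0 * nP);
      const double rate = k * (k - 1) / 2.0 * reff;
      if (rate <= 0.0) {
        if (!R_FINITE(tDiv)) stop("zero coalescence rate with infinite divergence time");
        t = tDiv; break;
      }
      const double dt = exp_rand() / rate;
      if (t + dt >= tDiv) { t = tDiv; break; }
      t += dt;
      int i = pick(k); int j = pick(k - 1); if (j >= i) ++j;
      tr.child1[made] = act[i]; tr.child2[made] = act[j]; tr.itime[made] = t;
      if (i > j) std::swap(i, j);
      act[i] = nextId; act.erase(act.begin() + j);
      ++nextId; ++made;
    }
  }

  // phase 2: single ancestral population of size nAnc
  if (made < n - 1) {
    if (!collapsed) {
      act.clear();
      act.insert(act.end(), inA.begin(), inA.end());
      act.insert(act.end(), inP.begin(), inP.end());
    }
    t = std::max(t, tDiv);
    while (made < n - 1) {
      const int k = (int)act.size();
      const double rate = k * (k - 1) / 2.0 / (2.0 * nAnc);
      t += exp_rand() / rate;
      int i = pick(k); int j = pick(k - 1); if (j >= i) ++j;
      tr.child1[made] = act[i]; tr.child2[made] = act[j]; tr.itime[made] = t;
      if (i > j) std::swap(i, j);
      act[i] = nextId; act.erase(act.begin() + j);
      ++nextId; ++made;
    }
  }
}

// per-node time (leaves at 0), parent id (-1 for root)
void node_annot(const Tree& tr, std::vector<double>& ntime, std::vector<int>& parent,
                std::vector<int>& dA, std::vector<int>& dP) {
  const int n = tr.n, m = 2 * n - 1;
  ntime.assign(m, 0.0);
  parent.assign(m, -1);
  dA.assign(m, 0); dP.assign(m, 0);
  for (int i = 0; i < n; ++i) {
    if (tr.leafPop[i] == 0) dA[i] = 1; else dP[i] = 1;
  }
  for (int k = 0; k < n - 1; ++k) {
    const int id = n + k, a = tr.child1[k], b = tr.child2[k];
    ntime[id] = tr.itime[k];
    parent[a] = id; parent[b] = id;
    dA[id] = dA[a] + dA[b];
    dP[id] = dP[a] + dP[b];
  }
}

Ctrl as_ctrl(List control) {
  Ctrl c;
  c.strongFactor = as<double>(control["strong_factor"]);
  c.relaxTime = as<double>(control["relax_time"]);
  c.maxExactEvents = as<double>(control["max_exact_events"]);
  return c;
}

} // namespace

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(double nAnc, double nA, double nP, double tDiv,
                       double mPA, double mAP, int sampA, int sampP,
                       List control) {
  RNGScope scope;
  Ctrl ctl = as_ctrl(control);
  Tree tr;
  sim_tree(nAnc, nA, nP, tDiv, mPA, mAP, sampA, sampP, ctl, tr);
  const int n = tr.n;
  IntegerMatrix merges(n - 1, 2);
  NumericVector times(n - 1);
  for (int k = 0; k < n - 1; ++k) {
    merges(k, 0) = tr.child1[k] + 1;   // 1-based for R
    merges(k, 1) = tr.child2[k] + 1;
    times[k] = tr.itime[k];
  }
  IntegerVector lp(n);
  for (int i = 0; i < n; ++i) lp[i] = tr.leafPop[i];
  std::vector<double> ntime; std::vector<int> parent, dA, dP;
  node_annot(tr, ntime, parent, dA, dP);
  double ltot = 0.0;
  for (int i = 0; i < 2 * n - 2; ++i) ltot += ntime[parent[i]] - ntime[i];
  return List::create(_["merges"] = merges, _["times"] = times,
                      _["leaf_pop"] = lp, _["total_length"] = ltot);
}

// batch of full coalescence-time vectors (reps x (n-1)); used for calibration
// [[Rcpp::export(name = ".sim_coal_times_cpp")]]
NumericMatrix sim_coal_times_cpp(double nAnc, double nA, double nP, double tDiv,
                                 double mPA, double mAP, int sampA, int sampP,
                                 int reps, List control) {
  RNGScope scope;
  Ctrl ctl = as_ctrl(control);
  const int n = sampA + sampP;
  NumericMatrix out(reps, n - 1);
  Tree tr;
  for (int r = 0; r < reps; ++r) {
    sim_tree(nAnc, nA, nP, tDiv, mPA, mAP, sampA, sampP, ctl, tr);
    for (int k = 0; k < n - 1; ++k) out(r, k) = tr.itime[k];
  }
  return out;
}

// Monte-Carlo estimate of the joint SFS law of segregating sites: over ngen
// independent genealogies, accumulates the total branch length subtending
// each (derived-in-A, derived-in-P) configuration. Under infinite sites the
// probability that a SNP shows configuration (i, j) is
// E[L_{ij}] / E[L_tot]; the length-weighted ratio of sums is the unbiased
// estimator (per-tree single-mutation sampling would estimate the biased
// E[L_ij / L_tot] instead). Also returns the mean total branch length, used
// for fixed-mu anchoring of absolute population sizes.
// [[Rcpp::export(name = ".sim_joint_sfs_cpp")]]
List sim_joint_sfs_cpp(double nAnc, double nA, double nP, double tDiv,
                       double mPA, double mAP, int sampA, int sampP,
                       double ngen, List control) {
  RNGScope scope;
  Ctrl ctl = as_ctrl(control);
  const int n = sampA + sampP;
  NumericMatrix lengths(sampA + 1, sampP + 1);
  double sumL = 0.0;
  Tree tr;
  std::vector<double> ntime; std::vector<int> parent, dA, dP;
  const long B = (long)ngen;
  for (long s = 0; s < B; ++s) {
    sim_tree(nAnc, nA, nP, tDiv, mPA, mAP, sampA, sampP, ctl, tr);
    node_annot(tr, ntime, parent, dA, dP);
    for (int i = 0; i < 2 * n - 2; ++i) {
      const double len = ntime[parent[i]] - ntime[i];
      lengths(dA[i], dP[i]) += len;
      sumL += len;
    }
  }
  return List::create(_["lengths"] = lengths,
                      _["mean_total_length"] = B > 0 ? sumL / B : NA_REAL);
}

// Infinite-sites haplotype data: nLoci independent non-recombining loci of
// locusLen sites each; mutations Poisson(mu * locusLen * total branch length),
// each assigned a distinct position and a branch proportional to its length.
// Returns a 0/1 haplotype-by-SNP matrix with locus index and position.
// [[Rcpp::export(name = ".sim_haplotypes_cpp")]]
List sim_haplotypes_cpp(double nAnc, double nA, double nP, double tDiv,
                        double mPA, double mAP, int sampA, int sampP,
                        int nLoci, double locusLen, double mu, List control) {
  RNGScope scope;
  Ctrl ctl = as_ctrl(control);
  const int n = sampA + sampP;
  std::vector<int> locusIdx, posIdx;
  std::vector<std::vector<char> > cols;   // one 0/1 column per SNP
  Tree tr;
  std::vector<double> ntime; std::vector<int> parent, dA, dP;
  std::vector<int> stack, leaves;
  for (int l = 0; l < nLoci; ++l) {
    sim_tree(nAnc, nA, nP, tDiv, mPA, mAP, sampA, sampP, ctl, tr);
    node_annot(tr, ntime, parent, dA, dP);
    double ltot = 0.0;
    for (int i = 0; i < 2 * n - 2; ++i) ltot += ntime[parent[i]] - ntime[i];
    const int nmut = (int)R::rpois(mu * locusLen * ltot);
    if (nmut == 0) continue;
    std::vector<int> positions;
    for (int m = 0; m < nmut; ++m) {
      int p;
      do {
        p = (int)(unif_rand() * locusLen) + 1;
      } while (std::find(positions.begin(), positions.end(), p) != positions.end());
      positions.push_back(p);
    }
    std::sort(positions.begin(), positions.end());
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * ltot;
      int hit = 2 * n - 3;
      for (int i = 0; i < 2 * n - 2; ++i) {
        u -= ntime[parent[i]] - ntime[i];
        if (u <= 0.0) { hit = i; break; }
      }
      // collect sampled leaves below 'hit'
      std::vector<char> col(n, 0);
      stack.clear(); stack.push_back(hit);
      while (!stack.empty()) {
        const int v = stack.back(); stack.pop_back();
        if (v < n) col[v] = 1;
        else { stack.push_back(tr.child1[v - n]); stack.push_back(tr.child2[v - n]); }
      }
      locusIdx.push_back(l + 1);
      posIdx.push_back(positions[m]);
      cols.push_back(col);
    }
  }
  const int S = (int)cols.size();
  IntegerMatrix geno(n, S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) geno(i, s) = cols[s][i];
  return List::create(_["haplotypes"] = geno,
                      _["locus"] = wrap(locusIdx),
                      _["pos"] = wrap(posIdx));
}
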