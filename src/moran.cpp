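// Moran model with recombination: exact event-loop simulator.
//
// The population is represented as genotype classes with counts; wildtype is
// class 0. Per event, two parents are drawn uniformly with replacement, a
// single crossover may fall in one interval of the linked block, each
// unlinked locus is transmitted from either parent with probability 1/2,
// and the offspring replaces a victim drawn with probability proportional
// to 1 - sigma (all draws with replacement; the offspring enters only after
// the victim is removed). Events in which both parents and the victim all
// belong to the current majority class change nothing (recombination
// between identical haplotypes reproduces them) and are skipped by
// sampling the conditional distribution of the remaining event types, so
// the cost of a replicate is proportional to the number of state-changing
// events rather than to N per unit of time.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Cls {
  uint32_t linked;    // bits 0..I-1 left alleles, bit I beneficial, I+1..I+J right
  uint32_t unlinked;  // F presence bits
  double sigma;
  double n;
};

struct Model {
  int N, I, J, F;
  std::vector<double> chiL, chiR;   // crossover interval probabilities
  double chi_tot;
  bool additive;
  double sben, u_eff;
  std::vector<double> left_eff, right_eff;
  std::vector<double> sig_table;    // (I+1)*(J+1)*(F+1), col-major
  uint32_t ben_bit, left_mask, right_mask;

  double fitness(uint32_t linked, uint32_t unl) const {
    bool has_ben = (linked & ben_bit) != 0;
    if (additive) {
      double s = has_ben ? sben : 0.0;
      uint32_t lb = linked & left_mask;
      while (lb) { int b = __builtin_ctz(lb); s -= left_eff[b]; lb &= lb - 1; }
      uint32_t rb = linked & right_mask;
      while (rb) { int b = __builtin_ctz(rb); s -= right_eff[b - (I + 1)]; rb &= rb - 1; }
      s -= u_eff * __builtin_popcount(unl);
      return s;
    }
    int i = __builtin_popcount(linked & left_mask);
    int j = __builtin_popcount(linked & right_mask);
    int f = __builtin_popcount(unl);
    double s = sig_table[i + (I + 1) * (j + (J + 1) * f)];
    if (!has_ben) s -= sig_table[0];
    return s;
  }
};

struct Pop {
  std::vector<Cls> cls;                       // cls[0] = wildtype
  std::unordered_map<uint64_t, int> index;
  double W;          // sum n * (1 - sigma)
  double nben;       // beneficial-allele copies
  std::vector<double> cnt_ij;  // beneficial carriers per (i,j) class

  static uint64_t key(uint32_t l, uint32_t u) {
    return (uint64_t)l | ((uint64_t)u << 32);
  }
};

class Sim {
public:
  Model md;

  void init(Pop &pop, uint32_t founder_linked, uint32_t founder_unl) const {
    pop.cls.clear(); pop.index.clear();
    pop.cls.push_back({0u, 0u, 0.0, (double)(md.N - 1)});
    pop.index[Pop::key(0u, 0u)] = 0;
    double fs = md.fitness(founder_linked, founder_unl);
    pop.cls.push_back({founder_linked, founder_unl, fs, 1.0});
    pop.index[Pop::key(founder_linked, founder_unl)] = 1;
    pop.W = (md.N - 1) + (1.0 - fs);
    pop.nben = (founder_linked & md.ben_bit) ? 1.0 : 0.0;
    pop.cnt_ij.assign((md.I + 1) * (md.J + 1), 0.0);
    if (founder_linked & md.ben_bit) pop.cnt_ij[ij_index(founder_linked)] = 1.0;
  }

  int ij_index(uint32_t linked) const {
    int i = __builtin_popcount(linked & md.left_mask);
    int j = __builtin_popcount(linked & md.right_mask);
    return i + (md.I + 1) * j;
  }

  int sample_minor_by_n(const Pop &pop, int pivot, double n_min) const {
    double u = unif_rand() * n_min;
    int last = pivot == 0 ? 1 : 0;
    for (size_t c = 0; c < pop.cls.size(); ++c) {
      if ((int)c == pivot) continue;
      u -= pop.cls[c].n;
      if (u <= 0) return (int)c;
      last = (int)c;
    }
    return last;
  }

  int sample_minor_victim(const Pop &pop, int pivot, double w_min) const {
    double u = unif_rand() * w_min;
    int last = pivot == 0 ? 1 : 0;
    for (size_t c = 0; c < pop.cls.size(); ++c) {
      if ((int)c == pivot) continue;
      u -= pop.cls[c].n * (1.0 - pop.cls[c].sigma);
      if (u <= 0) return (int)c;
      last = (int)c;
    }
    return last;
  }

  // u is pre-drawn and < chi_tot (a crossover happens)
  uint32_t crossover_linked(double u, uint32_t g1, uint32_t g2) const {
    uint32_t outer = 0;
    for (int k = 0; k < md.I; ++k) {          // left interval k: alleles k+1..I
      u -= md.chiL[k];
      if (u < 0) { outer = md.left_mask & ~((1u << k) - 1u); break; }
    }
    if (!outer) {
      for (int k = 0; k < md.J; ++k) {        // right interval k: alleles k+1..J
        u -= md.chiR[k];
        if (u < 0) {
          outer = md.right_mask & ~((1u << (md.I + 1 + k)) - 1u);
          break;
        }
      }
    }
    uint32_t all = md.left_mask | md.ben_bit | md.right_mask;
    uint32_t inner = all & ~outer;
    if (unif_rand() < 0.5) std::swap(g1, g2); // transmitted product
    return (g1 & outer) | (g2 & inner);
  }

  uint32_t transmit_unlinked(uint32_t u1, uint32_t u2) const {
    if (md.F == 0 || u1 == u2) return u1;
    uint32_t r = (uint32_t)(unif_rand() * (double)(1u << md.F));
    if (r >= (1u << md.F)) r = (1u << md.F) - 1u;
    return (u1 & r) | (u2 & ~r);
  }

  void change_count(Pop &pop, int c, double d) const {
    Cls &cl = pop.cls[c];
    cl.n += d;
    pop.W += d * (1.0 - cl.sigma);
    if (cl.linked & md.ben_bit) {
      pop.nben += d;
      pop.cnt_ij[ij_index(cl.linked)] += d;
    }
  }

  int add_offspring(Pop &pop, uint32_t linked, uint32_t unl) const {
    uint64_t k = Pop::key(linked, unl);
    auto it = pop.index.find(k);
    int c;
    if (it == pop.index.end()) {
      c = (int)pop.cls.size();
      pop.cls.push_back({linked, unl, md.fitness(linked, unl), 0.0});
      pop.index[k] = c;
    } else c = it->second;
    change_count(pop, c, 1.0);
    return c;
  }

  void prune(Pop &pop, int c) const {
    if (c == 0 || pop.cls[c].n > 0) return;
    int last = (int)pop.cls.size() - 1;
    pop.index.erase(Pop::key(pop.cls[c].linked, pop.cls[c].unlinked));
    if (c != last) {
      pop.cls[c] = pop.cls[last];
      pop.index[Pop::key(pop.cls[c].linked, pop.cls[c].unlinked)] = c;
    }
    pop.cls.pop_back();
  }

  // one replicate; returns: 0 lost, 1 success (threshold mode),
  // 2 fixed (reports linked class), -1 non-converged
  int replicate(Pop &pop, uint32_t founder_linked, uint32_t founder_unl,
                double thresh_count, double first_count,
                long long max_events,
                int &fixed_i, int &fixed_j, int &first_i, int &first_j) const {
    init(pop, founder_linked, founder_unl);
    bool first_done = first_count <= 0;
    first_i = first_j = -1;
    for (long long ev = 0; ev < max_events; ++ev) {
      // pivot = majority class; (pivot, pivot, pivot) events are no-ops
      int pivot = 0;
      for (size_t c = 1; c < pop.cls.size(); ++c)
        if (pop.cls[c].n > pop.cls[pivot].n) pivot = (int)c;
      double n_piv = pop.cls[pivot].n;
      double w_piv = n_piv * (1.0 - pop.cls[pivot].sigma);
      double pa = n_piv / md.N;
      double pv = w_piv / pop.W;
      double qa = 1.0 - pa, qv = 1.0 - pv;
      double w[7] = { pa * pa * qv, pa * qa * pv, pa * qa * qv,
                      qa * pa * pv, qa * pa * qv, qa * qa * pv, qa * qa * qv };
      double tot = 0; for (double x : w) tot += x;
      if (tot <= 0) {
        // population fully monomorphic for the pivot class
        if (pop.cls[pivot].linked & md.ben_bit) {
          fixed_i = __builtin_popcount(pop.cls[pivot].linked & md.left_mask);
          fixed_j = __builtin_popcount(pop.cls[pivot].linked & md.right_mask);
          return 2;
        }
        return 0;
      }
      double u = unif_rand() * tot;
      int combo = 0;
      for (; combo < 6; ++combo) { u -= w[combo]; if (u <= 0) break; }
      bool p1m = combo >= 3, p2m = (combo == 1 || combo == 2 || combo >= 5);
      bool vm = (combo == 0 || combo == 2 || combo == 4 || combo == 6);

      double n_min = md.N - n_piv;
      double w_min = pop.W - w_piv;
      int c1 = p1m ? sample_minor_by_n(pop, pivot, n_min) : pivot;
      int c2 = p2m ? sample_minor_by_n(pop, pivot, n_min) : pivot;
      int cv = vm ? sample_minor_victim(pop, pivot, w_min) : pivot;

      change_count(pop, cv, -1.0);
      if (c1 == c2) {
        // identical parents reproduce their genotype exactly
        change_count(pop, c1, 1.0);
      } else {
        double ur = unif_rand();
        if (ur >= md.chi_tot) {               // no crossover: copy one parent
          int cp = (unif_rand() < 0.5) ? c1 : c2;
          if (md.F == 0 || pop.cls[c1].unlinked == pop.cls[c2].unlinked) {
            change_count(pop, cp, 1.0);
          } else {
            uint32_t off_u = transmit_unlinked(pop.cls[c1].unlinked,
                                               pop.cls[c2].unlinked);
            if (off_u == pop.cls[cp].unlinked) change_count(pop, cp, 1.0);
            else add_offspring(pop, pop.cls[cp].linked, off_u);
          }
        } else {
          uint32_t off_l = crossover_linked(ur, pop.cls[c1].linked,
                                            pop.cls[c2].linked);
          uint32_t off_u = transmit_unlinked(pop.cls[c1].unlinked,
                                             pop.cls[c2].unlinked);
          add_offspring(pop, off_l, off_u);
        }
      }
      prune(pop, cv);

      if (pop.nben <= 0) return 0;
      if (!first_done) {
        for (size_t c = 0; c < pop.cnt_ij.size(); ++c)
          if (pop.cnt_ij[c] >= first_count) {
            first_i = (int)(c % (md.I + 1));
            first_j = (int)(c / (md.I + 1));
            first_done = true;
            break;
          }
      }
      if (thresh_count > 0 && pop.nben >= thresh_count) return 1;
      if (pop.nben >= md.N) {
        // monomorphic at the beneficial locus; fixed once one linked
        // haplotype (ignoring unlinked loci) carries everyone
        uint32_t l0 = 0; bool mono = true, have = false;
        for (const Cls &cl : pop.cls) {
          if (cl.n <= 0) continue;
          if (!have) { l0 = cl.linked; have = true; }
          else if (cl.linked != l0) { mono = false; break; }
        }
        if (mono) {
          fixed_i = __builtin_popcount(l0 & md.left_mask);
          fixed_j = __builtin_popcount(l0 & md.right_mask);
          return 2;
        }
      }
    }
    return -1;
  }
};

Model build_model(int N, int I, int J, int F,
                  NumericVector chiL, NumericVector chiR,
                  bool additive, double sben,
                  NumericVector left_eff, NumericVector right_eff,
                  double u_eff, NumericVector sig_table) {
  if (I + 1 + J > 31) stop("linked block too wide for the simulator");
  if (F > 20) stop("too many unlinked loci for the simulator");
  Model md;
  md.N = N; md.I = I; md.J = J; md.F = F;
  md.chiL = as<std::vector<double>>(chiL);
  md.chiR = as<std::vector<double>>(chiR);
  md.chi_tot = 0;
  for (double x : md.chiL) md.chi_tot += x;
  for (double x : md.chiR) md.chi_tot += x;
  md.additive = additive;
  md.sben = sben; md.u_eff = u_eff;
  md.left_eff = as<std::vector<double>>(left_eff);
  md.right_eff = as<std::vector<double>>(right_eff);
  md.sig_table = as<std::vector<double>>(sig_table);
  md.ben_bit = 1u << I;
  md.left_mask = I > 0 ? ((1u << I) - 1u) : 0u;
  md.right_mask = 0u;
  for (int k = 0; k < J; ++k) md.right_mask |= 1u << (I + 1 + k);
  return md;
}

} // namespace

// [[Rcpp::export(name = ".moran_run")]]
List moran_run(int N, int I, int J, int F,
               NumericVector chiL, NumericVector chiR,
               bool additive, double sben,
               NumericVector left_eff, NumericVector right_eff,
               double u_eff, NumericVector sig_table,
               int mode,                 // 0: introgression, 1: conditioned fixation
               double replicates,        // mode 0: attempts; mode 1: target successes
               double max_attempts,
               double thresh_count,      // mode 0: early success threshold (0 = run to fixation)
               double first_count,       // record first class reaching this count (0 = off)
               double max_events) {
  Sim sim;
  sim.md = build_model(N, I, J, F, chiL, chiR, additive, sben,
                       left_eff, right_eff, u_eff, sig_table);
  uint32_t founder_l = sim.md.left_mask | sim.md.ben_bit | sim.md.right_mask;
  uint32_t founder_u = F > 0 ? ((1u << F) - 1u) : 0u;

  Pop pop;
  double n_success = 0, n_attempts = 0, n_nonconv = 0;
  std::vector<int> fi, fj, firsti, firstj;
  long long maxev = (long long)max_events;

  while (true) {
    if (mode == 0 && n_attempts >= replicates) break;
    if (mode == 1 && (n_success >= replicates || n_attempts >= max_attempts)) break;
    if (((long long)n_attempts & 1023) == 0) Rcpp::checkUserInterrupt();
    int xi, xj, f1, f2;
    int out = sim.replicate(pop, founder_l, founder_u,
                            mode == 0 ? thresh_count : 0.0,
                            first_count, maxev, xi, xj, f1, f2);
    n_attempts += 1;
    if (out < 0) { n_nonconv += 1; continue; }
    if (out > 0) {
      n_success += 1;
      if (out == 2) { fi.push_back(xi); fj.push_back(xj); }
      if (first_count > 0) { firsti.push_back(f1); firstj.push_back(f2); }
    }
  }
  return List::create(_["attempts"] = n_attempts,
                      _["successes"] = n_success,
                      _["nonconverged"] = n_nonconv,
                      _["fixed_i"] = wrap(fi), _["fixed_j"] = wrap(fj),
                      _["first_i"] = wrap(firsti), _["first_j"] = wrap(firstj));
}
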