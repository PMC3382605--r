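// Fast replicate engine.  Mirrors the pure-R reference engine draw for draw:
// every stochastic decision consumes uniforms from R's global RNG stream
// (unif_rand) with the same arithmetic and in the same order as the R code,
// so both engines produce bitwise-identical trajectories from the same seed.
//
// Draw contract per generation:
//   game stage   : per deme (ascending id), one Fisher-Yates shuffle of the
//                  roster (n - 1 index draws; none for n < 2)
//   migration    : one uniform per individual in roster order (decision),
//                  then one index draw per migrant in roster order
//                  (destination; skipped in degree-0 demes)
//   selection    : per deme, one index draw per tie event while culling;
//                  one roulette uniform per daughter while expanding
//                  (uniform index draw instead when all weights are zero)

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Ind {
  int s;     // 1 = cooperate, 0 = defect
  double f;  // fitness
};

// index in 1..k, one uniform; identical to R's 1L + as.integer(runif(1) * k)
static inline int rng_index(int k) {
  int j = 1 + (int)(unif_rand() * (double)k);
  if (j > k) j = k;
  return j;
}

// Fisher-Yates permutation of 0..n-1, matching the R loop on 1..n
static void rng_perm(std::vector<int> &p) {
  int n = (int)p.size();
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n; i >= 2; --i) {
    int j = rng_index(i);
    int tmp = p[i - 1];
    p[i - 1] = p[j - 1];
    p[j - 1] = tmp;
  }
}

static inline double payoff_of(int s, int o, double pT, double pR, double pP,
                               double pS) {
  if (s == 1) return o == 1 ? pR : pS;
  return o == 1 ? pT : pP;
}

// plain double accumulation, matching the R plain_mean()
static double plain_mean(const std::vector<double> &x, int from, int len) {
  double s = 0.0;
  for (int i = 0; i < len; ++i) s += x[from + i];
  return s / (double)len;
}

// [[Rcpp::export]]
List cpp_run_engine(IntegerVector strategy, NumericVector fitness,
                    IntegerVector deme, int D, int N0, List neighbors,
                    double m, double E, double w, double pT, double pR,
                    double pP, double pS, bool unpaired_decay,
                    double newborn_fitness, int max_generations, int window,
                    double tol, bool detect, int start_generation) {
  // adjacency (1-based ids in, 0-based here)
  std::vector< std::vector<int> > nbr(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector nd = neighbors[d];
    nbr[d].reserve(nd.size());
    for (int k = 0; k < nd.size(); ++k) nbr[d].push_back(nd[k] - 1);
  }

  // rosters (input is sorted by deme, roster order preserved)
  std::vector< std::vector<Ind> > ros(D);
  int n_in = strategy.size();
  for (int i = 0; i < n_in; ++i) {
    Ind ind;
    ind.s = strategy[i];
    ind.f = fitness[i];
    ros[deme[i] - 1].push_back(ind);
  }

  std::vector<int> traj_gen;
  std::vector<double> traj_rho;
  std::vector<int> traj_total;
  std::vector<int> traj_occ;
  int outcome = 4;  // UNRESOLVED
  double final_rho = NA_REAL;
  int generation = start_generation;

  std::vector<int> perm;
  std::vector<char> wants;
  std::vector<int> alive;
  std::vector<double> cum;

  for (int g = 0; g < max_generations; ++g) {
    // ---- game stage ----
    for (int d = 0; d < D; ++d) {
      std::vector<Ind> &v = ros[d];
      int n = (int)v.size();
      if (n == 0) continue;
      perm.resize(n);
      if (n >= 2) rng_perm(perm); else perm[0] = 0;
      int npair = n / 2;
      for (int t = 0; t < npair; ++t) {
        int ia = perm[2 * t];
        int ib = perm[2 * t + 1];
        double ga = payoff_of(v[ia].s, v[ib].s, pT, pR, pP, pS);
        double gb = payoff_of(v[ib].s, v[ia].s, pT, pR, pP, pS);
        v[ia].f = (1.0 - w) * v[ia].f + w * ga;
        v[ib].f = (1.0 - w) * v[ib].f + w * gb;
      }
      if (n % 2 == 1 && unpaired_decay) {
        int il = perm[n - 1];
        v[il].f = (1.0 - w) * v[il].f + w * 0.0;
      }
    }

    // ---- migration ----
    if (m > 0.0) {
      int total = 0;
      for (int d = 0; d < D; ++d) total += (int)ros[d].size();
      if (total > 0) {
        wants.resize(total);
        for (int i = 0; i < total; ++i) wants[i] = unif_rand() < m ? 1 : 0;
        std::vector< std::vector<Ind> > stay(D), incoming(D);
        int i = 0;
        for (int d = 0; d < D; ++d) {
          int n = (int)ros[d].size();
          int k = (int)nbr[d].size();
          for (int t = 0; t < n; ++t, ++i) {
            if (wants[i] && k > 0) {
              int j = rng_index(k);
              incoming[nbr[d][j - 1]].push_back(ros[d][t]);
            } else {
              stay[d].push_back(ros[d][t]);
            }
          }
        }
        for (int d = 0; d < D; ++d) {
          ros[d].swap(stay[d]);
          for (size_t t = 0; t < incoming[d].size(); ++t)
            ros[d].push_back(incoming[d][t]);
        }
      }
    }

    // ---- selection ----
    for (int d = 0; d < D; ++d) {
      std::vector<Ind> &v = ros[d];
      // threshold elimination (strict: f == E survives)
      std::vector<Ind> surv;
      surv.reserve(v.size());
      for (size_t t = 0; t < v.size(); ++t)
        if (v[t].f >= E) surv.push_back(v[t]);
      int n = (int)surv.size();
      if (n > N0) {
        // repeated least-fit removal, uniform tie-break
        std::vector<char> live(n, 1);
        for (int r = 0; r < n - N0; ++r) {
          double minval = R_PosInf;
          for (int t = 0; t < n; ++t)
            if (live[t] && surv[t].f < minval) minval = surv[t].f;
          alive.clear();
          for (int t = 0; t < n; ++t)
            if (live[t] && surv[t].f == minval) alive.push_back(t);
          int pick = (alive.size() > 1)
                         ? alive[rng_index((int)alive.size()) - 1]
                         : alive[0];
          live[pick] = 0;
        }
        std::vector<Ind> kept;
        kept.reserve(N0);
        for (int t = 0; t < n; ++t)
          if (live[t]) kept.push_back(surv[t]);
        surv.swap(kept);
      } else if (n > 0 && n < N0) {
        // fitness-proportional expansion from the pre-expansion survivors
        cum.resize(n);
        double tot = 0.0;
        for (int t = 0; t < n; ++t) {
          double wt = surv[t].f;
          if (wt < 0.0) wt = 0.0;
          tot += wt;
          cum[t] = tot;
        }
        int births = N0 - n;
        for (int b = 0; b < births; ++b) {
          int parent;
          if (tot <= 0.0) {
            parent = rng_index(n) - 1;
          } else {
            double u = unif_rand() * tot;
            parent = n - 1;
            for (int t = 0; t < n; ++t) {
              if (u < cum[t]) { parent = t; break; }
            }
          }
          Ind daughter;
          daughter.s = surv[parent].s;
          daughter.f = newborn_fitness;
          surv.push_back(daughter);
        }
      }
      v.swap(surv);
    }

    // ---- census ----
    generation += 1;
    int total = 0, nc = 0, occ = 0;
    for (int d = 0; d < D; ++d) {
      int n = (int)ros[d].size();
      total += n;
      if (n > 0) occ += 1;
      for (int t = 0; t < n; ++t) nc += ros[d][t].s;
    }
    double rho = total > 0 ? (double)nc / (double)total : 0.0;
    traj_gen.push_back(generation);
    traj_rho.push_back(rho);
    traj_total.push_back(total);
    traj_occ.push_back(occ);

    if (detect) {
      if (total == 0) { outcome = 1; final_rho = 0.0; break; }
      if (nc == total) { outcome = 2; final_rho = 1.0; break; }
      int nrec = (int)traj_rho.size();
      if (nc > 0 && nrec >= 2 * window) {
        double m2 = plain_mean(traj_rho, nrec - window, window);
        double m1 = plain_mean(traj_rho, nrec - 2 * window, window);
        double diff = m2 - m1;
        if (diff < 0) diff = -diff;
        if (diff <= tol) { outcome = 3; final_rho = m2; break; }
      }
    }
  }

  // flatten final state in deme order, roster order
  int total = 0;
  for (int d = 0; d < D; ++d) total += (int)ros[d].size();
  IntegerVector out_s(total), out_d(total);
  NumericVector out_f(total);
  int i = 0;
  for (int d = 0; d < D; ++d) {
    for (size_t t = 0; t < ros[d].size(); ++t, ++i) {
      out_s[i] = ros[d][t].s;
      out_f[i] = ros[d][t].f;
      out_d[i] = d + 1;
    }
  }

  return List::create(
      _["strategy"] = out_s, _["fitness"] = out_f, _["deme"] = out_d,
      _["generation"] = generation, _["traj_gen"] = wrap(traj_gen),
      _["traj_rho"] = wrap(traj_rho), _["traj_total"] = wrap(traj_total),
      _["traj_occ"] = wrap(traj_occ), _["outcome"] = outcome,
      _["final_rho"] = final_rho);
}
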