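#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Site state codes shared with the R side:
//   domain: 0 outside, 1 lumen, 2 wall
//   occupant: 0 none, 1 cSMC, 2 sSMC, 3 EC
// Sites are flat indices s = i + nx*(j + ny*k), 0-based here, 1-based in R.

static const double ECM_TOL = 1e-9;

struct Grid {
  int nx, ny, nz;
  long n;
  std::vector<int> off;   // flat offsets (valid away from borders)
  std::vector<int> di, dj, dk;
  Grid(IntegerVector dims, int stencil) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    n = (long)nx * ny * nz;
    for (int z = -1; z <= 1; ++z)
      for (int y = -1; y <= 1; ++y)
        for (int x = -1; x <= 1; ++x) {
          int m = std::abs(x) + std::abs(y) + std::abs(z);
          if (m == 0) continue;
          if (stencil == 6 && m > 1) continue;
          if (stencil == 18 && m > 2) continue;
          di.push_back(x); dj.push_back(y); dk.push_back(z);
          off.push_back(x + nx * (y + ny * z));
        }
  }
  int noff() const { return (int)off.size(); }
  inline void coords(long s, int& i, int& j, int& k) const {
    i = (int)(s % nx); j = (int)((s / nx) % ny); k = (int)(s / ((long)nx * ny));
  }
  // collect in-grid neighbours of s into nb; returns count
  inline int neighbours(long s, long* nb) const {
    int i, j, k, cnt = 0;
    coords(s, i, j, k);
    for (int t = 0; t < noff(); ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      nb[cnt++] = s + off[t] ;
    }
    return cnt;
  }
};

static inline bool adj_ecm(const Grid& G, const double* ecm, long s) {
  long nb[26];
  int nn = G.neighbours(s, nb);
  for (int t = 0; t < nn; ++t)
    if (ecm[nb[t]] > ECM_TOL) return true;
  return false;
}

// destination rule shared by migration and SMC daughter placement:
// the site itself carries matrix, or touches matrix
static inline bool anchored(const Grid& G, const double* ecm, long s) {
  return ecm[s] > ECM_TOL || adj_ecm(G, ecm, s);
}

static inline int runif_int(int n) {
  int r = (int)(unif_rand() * n);
  return r >= n ? n - 1 : r;
}

// stochastic rounding: floor(x) plus one extra with probability frac(x)
static inline int srnd(double x) {
  int b = (int)std::floor(x);
  double f = x - b;
  if (f > 0 && unif_rand() < f) ++b;
  return b;
}

// qualifying lumen-surface site: lumen domain, matrix-free, touching matrix
static inline bool is_surface(const Grid& G, const int* dom, const double* ecm, long s) {
  return dom[s] == 1 && ecm[s] <= ECM_TOL && adj_ecm(G, ecm, s);
}

// [[Rcpp::export]]
IntegerVector cpp_surface_sites(IntegerVector domain, NumericVector ecm,
                                IntegerVector dims, int stencil) {
  Grid G(dims, stencil);
  const int* dom = INTEGER(domain);
  const double* e = REAL(ecm);
  std::vector<int> out;
  for (long s = 0; s < G.n; ++s)
    if (is_surface(G, dom, e, s)) out.push_back((int)(s + 1));
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_surface_census(IntegerVector domain, NumericVector ecm, IntegerVector occ,
                        IntegerVector dims, int stencil) {
  Grid G(dims, stencil);
  const int* dom = INTEGER(domain);
  const double* e = REAL(ecm);
  const int* o = INTEGER(occ);
  long unhealed = 0, total = 0;
  IntegerVector free_lumen(G.nz);
  for (long s = 0; s < G.n; ++s) {
    if (dom[s] == 1 && e[s] <= ECM_TOL && o[s] == 0)
      free_lumen[(int)(s / ((long)G.nx * G.ny))]++;
    if (is_surface(G, dom, e, s)) {
      ++total;
      if (o[s] != 3) ++unhealed;
    }
  }
  return List::create(_["unhealed"] = (double)unhealed, _["total"] = (double)total,
                      _["free_lumen_by_slice"] = free_lumen);
}

// Advance the simulation by up to ndays one-day increments.
//
// Daily order: (1) matrix degradation; (2) phenotype update of every SMC;
// (3) cell actions in sub-daily passes: each cell's per-day attempt budget
// (stochastic rounding of v_SMC/dl migration steps and p_SMC divisions for
// sSMCs, p_EC divisions for ECs) is consumed one attempt per pass, in a
// freshly shuffled cell order each pass; daughters enter the schedule at the
// pass after their birth and unused attempts lapse at day end; (4) each sSMC
// alive at dawn deposits ECM at its site; (5) metrics and termination.
// [[Rcpp::export]]
List cpp_run_days(IntegerVector domain, NumericVector ecm_, NumericVector mdf_,
                  NumericVector g_, IntegerVector occ_, IntegerVector dims,
                  List par, int ndays, bool record_slices,
                  bool stop_on_termination) {
  int stencil = as<int>(par["stencil"]);
  Grid G(dims, stencil);
  const int* dom = INTEGER(domain);

  NumericVector ecmv = clone(ecm_), mdfv = clone(mdf_), gv = clone(g_);
  IntegerVector occv = clone(occ_);
  double* ecm = REAL(ecmv);
  double* mdf = REAL(mdfv);
  double* g = REAL(gv);
  int* occ = INTEGER(occv);

  const double dl = as<double>(par["dl"]);
  const double v_smc = as<double>(par["v_smc"]);
  const double p_smc = as<double>(par["p_smc"]);
  const double p_ec = as<double>(par["p_ec"]);
  const double c_ecm = as<double>(par["c_ecm"]);
  const double c_deg = as<double>(par["c_deg"]);
  const double g_crit = as<double>(par["g_crit"]);
  const double c_smc_crit = as<double>(par["c_smc_crit"]);
  const int k_lo = as<int>(par["k_lo"]);   // 0-based slice range for the
  const int k_hi = as<int>(par["k_hi"]);   // occlusion check; -1 disables
  const double mig_rate = v_smc / dl;

  RNGScope scope;

  // cell registry from occupancy
  std::vector<long> csite;
  std::vector<signed char> ckind;
  for (long s = 0; s < G.n; ++s)
    if (occ[s] != 0) { csite.push_back(s); ckind.push_back((signed char)occ[s]); }

  // sites that can degrade: MDF is never produced during a run
  std::vector<long> mdf_sites;
  for (long s = 0; s < G.n; ++s)
    if (mdf[s] > ECM_TOL) mdf_sites.push_back(s);

  double g_total = 0.0;
  for (long s = 0; s < G.n; ++s) g_total += g[s];

  // per-slice count of matrix-bearing sites, maintained incrementally
  std::vector<long> slice_ecm(G.nz, 0);
  for (long s = 0; s < G.n; ++s)
    if (ecm[s] > ECM_TOL) slice_ecm[(int)(s / ((long)G.nx * G.ny))]++;

  long unhealed = 0;
  std::vector<long> free_lumen(G.nz, 0);
  bool occluded_now = false;
  auto census = [&]() {
    unhealed = 0;
    std::fill(free_lumen.begin(), free_lumen.end(), 0L);
    for (long s = 0; s < G.n; ++s) {
      if (dom[s] == 1 && ecm[s] <= ECM_TOL && occ[s] == 0)
        free_lumen[(int)(s / ((long)G.nx * G.ny))]++;
      if (is_surface(G, dom, ecm, s) && occ[s] != 3) ++unhealed;
    }
    occluded_now = false;
    if (k_lo >= 0)
      for (int k = k_lo; k <= k_hi && !occluded_now; ++k)
        if (free_lumen[k] == 0) occluded_now = true;
  };
  census();

  // outputs
  std::vector<int> out_csmc, out_ssmc, out_ec, out_div_smc, out_div_ec, out_steps;
  std::vector<double> out_gtot;
  std::vector<long> out_slices;  // row-major day x nz
  std::string termination = "running";

  // per-day scratch
  std::vector<uint8_t> n_att, att_used;
  std::vector<uint64_t> pmask;      // bit p set => attempt p is a division
  std::vector<int> birth_pass;
  std::vector<int> order;

  auto set_ecm = [&](long s, double v) {
    bool was = ecm[s] > ECM_TOL, is = v > ECM_TOL;
    ecm[s] = v;
    if (was != is) slice_ecm[(int)(s / ((long)G.nx * G.ny))] += is ? 1 : -1;
  };

  int day = 0;
  for (; day < ndays; ++day) {
    bool ecm_changed = false;

    // (1) degradation: ECM and MDF co-resorb where both are present
    for (size_t t = 0; t < mdf_sites.size();) {
      long s = mdf_sites[t];
      if (ecm[s] > ECM_TOL) {
        double e2 = ecm[s] - c_deg;
        if (e2 < ECM_TOL) e2 = 0.0;
        set_ecm(s, e2);
        double m2 = mdf[s] - c_deg;
        if (m2 < ECM_TOL) m2 = 0.0;
        mdf[s] = m2;
        ecm_changed = true;
      }
      if (mdf[s] <= ECM_TOL) {
        mdf_sites[t] = mdf_sites.back();
        mdf_sites.pop_back();
      } else ++t;
    }

    size_t n_dawn = csite.size();

    // (2) phenotype: synthetic when the local matrix is not intact or the
    // neighbourhood is crowded; contractile otherwise (reversible)
    for (size_t c = 0; c < n_dawn; ++c) {
      if (ckind[c] == 3) continue;
      long s = csite[c];
      bool synth = ecm[s] < 1.0 - ECM_TOL;
      long nb[26];
      int nn = G.neighbours(s, nb);
      if (!synth) {
        for (int t = 0; t < nn; ++t) {
          double e = ecm[nb[t]];
          if (e > ECM_TOL && e < 1.0 - ECM_TOL) { synth = true; break; }
        }
      }
      if (!synth) {  // crowding test over the {site} + neighbours stencil
        int n_in = 1, n_smc = (occ[s] == 1 || occ[s] == 2) ? 1 : 0;
        for (int t = 0; t < nn; ++t) {
          if (dom[nb[t]] == 0) continue;
          ++n_in;
          if (occ[nb[t]] == 1 || occ[nb[t]] == 2) ++n_smc;
        }
        if ((double)n_smc / n_in >= c_smc_crit) synth = true;
      }
      ckind[c] = synth ? 2 : 1;
      occ[s] = synth ? 2 : 1;
    }

    // (3) attempt budgets, then sub-daily passes
    n_att.assign(n_dawn, 0);
    att_used.assign(n_dawn, 0);
    pmask.assign(n_dawn, 0);
    birth_pass.assign(n_dawn, 0);
    int n_passes = 0, div_smc = 0, div_ec = 0, steps = 0;
    for (size_t c = 0; c < n_dawn; ++c) {
      int na = 0;
      uint64_t pm = 0;
      if (ckind[c] == 2) {
        int nm = srnd(mig_rate), np = srnd(p_smc);
        na = nm + np;
        if (na > 63) na = 63;
        // scatter the np division attempts uniformly among the na slots
        for (int placed = 0; placed < np && placed < na;) {
          int slot = runif_int(na);
          if (!(pm >> slot & 1)) { pm |= (uint64_t)1 << slot; ++placed; }
        }
      } else if (ckind[c] == 3) {
        na = srnd(p_ec);
        if (na > 63) na = 63;
        pm = ~(uint64_t)0;  // every EC attempt is a division attempt
      }
      n_att[c] = (uint8_t)na;
      pmask[c] = pm;
      if (na > n_passes) n_passes = na;
    }

    for (int pass = 1; pass <= n_passes; ++pass) {
      order.clear();
      for (size_t c = 0; c < csite.size(); ++c)
        if (birth_pass[c] < pass && att_used[c] < n_att[c]) order.push_back((int)c);
      for (int t = (int)order.size() - 1; t > 0; --t)
        std::swap(order[t], order[runif_int(t + 1)]);

      for (size_t t = 0; t < order.size(); ++t) {
        int c = order[t];
        long s = csite[c];
        int slot = att_used[c]++;
        bool division = pmask[c] >> slot & 1;
        long nb[26];
        int nn = G.neighbours(s, nb);
        if (ckind[c] == 2 && !division) {
          // migration: one uniform draw over the neighbourhood, rejected
          // unless the target is free and matrix-anchored
          long s2 = nb[runif_int(nn)];
          if (dom[s2] != 0 && occ[s2] == 0 && anchored(G, ecm, s2)) {
            occ[s] = 0;
            occ[s2] = 2;
            csite[c] = s2;
            ++steps;
          }
        } else if (ckind[c] == 2) {
          // division funded by the local growth stimulus
          if (g[s] > g_crit) {
            long empties[26];
            int ne = 0;
            for (int q = 0; q < nn; ++q)
              if (dom[nb[q]] != 0 && occ[nb[q]] == 0) empties[ne++] = nb[q];
            if (ne > 0) {
              long s2 = empties[runif_int(ne)];
              if (anchored(G, ecm, s2)) {
                occ[s2] = 2;
                csite.push_back(s2);
                ckind.push_back(2);
                int nm = srnd(mig_rate), np = srnd(p_smc);
                int na = std::min(nm + np, 63);
                uint64_t pm = 0;
                for (int placed = 0; placed < np && placed < na;) {
                  int slot2 = runif_int(na);
                  if (!(pm >> slot2 & 1)) { pm |= (uint64_t)1 << slot2; ++placed; }
                }
                n_att.push_back((uint8_t)na);
                att_used.push_back(0);
                pmask.push_back(pm);
                birth_pass.push_back(pass);
                g[s] -= g_crit;
                if (g[s] < ECM_TOL) g[s] = 0.0;
                g_total -= g_crit;
                ++div_smc;
              }
            }
          }
        } else if (ckind[c] == 3) {
          // EC division: uniform draw over empty matrix-free positions,
          // rejected unless the position touches matrix (lumen surface)
          long empties[26];
          int ne = 0;
          for (int q = 0; q < nn; ++q)
            if (dom[nb[q]] != 0 && occ[nb[q]] == 0 && ecm[nb[q]] <= ECM_TOL)
              empties[ne++] = nb[q];
          if (ne > 0) {
            long s2 = empties[runif_int(ne)];
            if (adj_ecm(G, ecm, s2)) {
              occ[s2] = 3;
              csite.push_back(s2);
              ckind.push_back(3);
              int na = std::min(srnd(p_ec), 63);
              n_att.push_back((uint8_t)na);
              att_used.push_back(0);
              pmask.push_back(~(uint64_t)0);
              birth_pass.push_back(pass);
              ++div_ec;
              if (dom[s2] == 1) --unhealed;
            }
          }
        }
      }
    }

    // (4) matrix production by sSMCs alive at dawn
    for (size_t c = 0; c < n_dawn; ++c) {
      if (ckind[c] != 2) continue;
      long s = csite[c];
      if (ecm[s] < 1.0 - ECM_TOL) {
        double e2 = ecm[s] + c_ecm;
        if (e2 > 1.0 - ECM_TOL) e2 = 1.0;
        set_ecm(s, e2);
        ecm_changed = true;
      }
    }

    // (5) metrics and termination
    int nc = 0, ns = 0, nec = 0;
    for (size_t c = 0; c < csite.size(); ++c) {
      if (ckind[c] == 1) ++nc;
      else if (ckind[c] == 2) ++ns;
      else ++nec;
    }
    out_csmc.push_back(nc);
    out_ssmc.push_back(ns);
    out_ec.push_back(nec);
    out_div_smc.push_back(div_smc);
    out_div_ec.push_back(div_ec);
    out_steps.push_back(steps);
    out_gtot.push_back(g_total);
    if (record_slices)
      for (int k = 0; k < G.nz; ++k) out_slices.push_back(slice_ecm[k]);

    if (ecm_changed) census();
    if (occluded_now) {
      if (termination == "running") termination = "occluded";
    } else if (unhealed == 0 && termination == "running") {
      bool active = false;
      for (size_t c = 0; c < csite.size() && !active; ++c) {
        if (ckind[c] != 2) continue;
        long s = csite[c];
        if (g[s] > g_crit) { active = true; break; }
        long nb[26];
        int nn = G.neighbours(s, nb);
        for (int q = 0; q < nn; ++q)
          if (dom[nb[q]] != 0 && occ[nb[q]] == 0 && anchored(G, ecm, nb[q])) {
            active = true;
            break;
          }
      }
      if (!active) termination = "healed_equilibrium";
    }
    if (termination != "running" && stop_on_termination) { ++day; break; }
  }

  List out = List::create(
    _["ecm"] = ecmv, _["mdf"] = mdfv, _["g"] = gv, _["occ"] = occv,
    _["days_run"] = day,
    _["n_csmc"] = wrap(out_csmc), _["n_ssmc"] = wrap(out_ssmc),
    _["n_ec"] = wrap(out_ec),
    _["div_smc"] = wrap(out_div_smc), _["div_ec"] = wrap(out_div_ec),
    _["steps"] = wrap(out_steps), _["g_total"] = wrap(out_gtot),
    _["termination"] = termination);
  if (record_slices) {
    NumericMatrix sm((int)out_csmc.size(), G.nz);
    for (int d = 0; d < (int)out_csmc.size(); ++d)
      for (int k = 0; k < G.nz; ++k) sm(d, k) = (double)out_slices[(long)d * G.nz + k];
    out["slice_ecm"] = sm;
  }
  return out;
}
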