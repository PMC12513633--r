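// Exact Gillespie simulation of multi-mode RPA binding on an ssDNA lattice.
// Proteins occupy half-open footprints [start, start+mode) with mode 20
// (initial binding) or 30 (extended). Events and rates:
//   bind-20 at any start with >= 20 free sites       : k1 per eligible start
//   unbind a 20-mode protein                         : km1
//   extend 20 -> 30 (10 free sites downstream)       : k2
//   revert 30 -> 20                                  : km2
// Propensities are recomputed from the occupancy after every event, so the
// gap-eligibility rules (k1' = 0, k2' = 0 when the gap is too small) are
// enforced by construction. Uses R's RNG (seeded from the R side).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Prot { int start; int mode; };

static void check_state(const std::vector<Prot>& ps, int L) {
  int prev_end = 0;
  int n20 = 0, n30 = 0;
  for (size_t i = 0; i < ps.size(); ++i) {
    if (ps[i].start < prev_end || ps[i].start + ps[i].mode > L)
      stop("occupancy invariant violated: overlapping or out-of-range footprint");
    prev_end = ps[i].start + ps[i].mode;
    if (ps[i].mode == 20) ++n20; else ++n30;
  }
  if (20 * n20 + 30 * n30 > L) stop("occupancy invariant violated: coverage exceeds L");
}

// [[Rcpp::export(name = ".rpa_ssa_cpp")]]
List rpa_ssa_cpp(int L, double k1, double km1, double k2, double km2,
                 NumericVector grid, double horizon,
                 bool keep_log = false, bool debug = false) {
  std::vector<Prot> ps;            // sorted by start
  int n20 = 0, n30 = 0;
  const int J = grid.size();
  NumericMatrix out(J, 2);
  int jfill = 0;                   // next grid index to fill
  double t = 0.0;
  std::vector<double> log_t; std::vector<int> log_type, log_pos;

  while (true) {
    // --- propensities from scratch ---
    // gaps: [prev_end, next_start); eligible bind starts per gap = g - 19
    double nbind = 0.0;
    {
      int prev_end = 0;
      for (size_t i = 0; i <= ps.size(); ++i) {
        int next_start = (i < ps.size()) ? ps[i].start : L;
        int g = next_start - prev_end;
        if (g >= 20) nbind += g - 19;
        if (i < ps.size()) prev_end = ps[i].start + ps[i].mode;
      }
    }
    double a_bind = k1 * nbind;
    double a_unbind = km1 * n20;
    double a_revert = km2 * n30;
    // extension eligibility per 20-mode protein
    std::vector<int> ext_idx;
    if (k2 > 0) {
      for (size_t i = 0; i < ps.size(); ++i) {
        if (ps[i].mode != 20) continue;
        int end20 = ps[i].start + 20;
        int next_start = (i + 1 < ps.size()) ? ps[i + 1].start : L;
        if (next_start - end20 >= 10) ext_idx.push_back((int)i);
      }
    }
    double a_ext = k2 * ext_idx.size();
    double a0 = a_bind + a_unbind + a_ext + a_revert;

    double tnext = (a0 > 0.0) ? t + R::exp_rand() / a0 : R_PosInf;
    // sample the state onto grid points passed before the next event
    while (jfill < J && grid[jfill] < tnext && grid[jfill] <= horizon) {
      out(jfill, 0) = 20.0 * n20 / L;
      out(jfill, 1) = 30.0 * n30 / L;
      ++jfill;
    }
    if (tnext > horizon || a0 <= 0.0) break;
    t = tnext;

    double u = unif_rand() * a0;
    int type = -1, pos = -1;
    if (u < a_bind) {
      type = 0;
      // choose gap weighted by (g - 19), then a uniform offset within it
      double target = u / k1;   // in [0, nbind)
      int prev_end = 0; double acc = 0.0;
      for (size_t i = 0; i <= ps.size(); ++i) {
        int next_start = (i < ps.size()) ? ps[i].start : L;
        int g = next_start - prev_end;
        if (g >= 20) {
          if (target < acc + (g - 19)) {
            pos = prev_end + (int)(target - acc);
            break;
          }
          acc += g - 19;
        }
        if (i < ps.size()) prev_end = ps[i].start + ps[i].mode;
      }
      if (pos < 0) pos = L - 20;  // numeric edge guard
      Prot np; np.start = pos; np.mode = 20;
      ps.insert(std::upper_bound(ps.begin(), ps.end(), np,
                [](const Prot& a, const Prot& b){ return a.start < b.start; }), np);
      ++n20;
    } else if (u < a_bind + a_unbind) {
      type = 1;
      int which = std::min((int)((u - a_bind) / km1), n20 - 1);
      int seen = 0;
      for (size_t i = 0; i < ps.size(); ++i) {
        if (ps[i].mode == 20 && seen++ == which) {
          pos = ps[i].start;
          ps.erase(ps.begin() + i);
          break;
        }
      }
      --n20;
    } else if (u < a_bind + a_unbind + a_ext) {
      type = 2;
      int which = std::min((int)((u - a_bind - a_unbind) / k2),
                           (int)ext_idx.size() - 1);
      int i = ext_idx[which];
      pos = ps[i].start;
      ps[i].mode = 30;
      --n20; ++n30;
    } else {
      type = 3;
      int which = std::min((int)((u - a_bind - a_unbind - a_ext) / km2), n30 - 1);
      int seen = 0;
      for (size_t i = 0; i < ps.size(); ++i) {
        if (ps[i].mode == 30 && seen++ == which) {
          pos = ps[i].start;
          ps[i].mode = 20;
          break;
        }
      }
      --n30; ++n20;
    }
    if (debug) check_state(ps, L);
    if (keep_log) { log_t.push_back(t); log_type.push_back(type); log_pos.push_back(pos); }
  }
  // any remaining grid points (frozen state until horizon)
  while (jfill < J && grid[jfill] <= horizon) {
    out(jfill, 0) = 20.0 * n20 / L;
    out(jfill, 1) = 30.0 * n30 / L;
    ++jfill;
  }
  IntegerVector starts(ps.size()), modes(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) { starts[i] = ps[i].start; modes[i] = ps[i].mode; }
  List res = List::create(_["x"] = out, _["starts"] = starts, _["modes"] = modes);
  if (keep_log)
    res["events"] = DataFrame::create(_["t"] = log_t, _["type"] = log_type,
                                      _["pos"] = log_pos);
  return res;
}

// Propensity totals for an arbitrary configuration: the C++ counterpart of
// the R-level event enumeration, cross-checked in the tests.
// [[Rcpp::export(name = ".rpa_propensities_cpp")]]
NumericVector rpa_propensities_cpp(int L, IntegerVector starts, IntegerVector modes,
                                   double k1, double km1, double k2, double km2) {
  std::vector<Prot> ps(starts.size());
  for (int i = 0; i < starts.size(); ++i) { ps[i].start = starts[i]; ps[i].mode = modes[i]; }
  std::sort(ps.begin(), ps.end(), [](const Prot& a, const Prot& b){ return a.start < b.start; });
  check_state(ps, L);
  double nbind = 0.0; int n20 = 0, n30 = 0, next_ok = 0;
  int prev_end = 0;
  for (size_t i = 0; i <= ps.size(); ++i) {
    int next_start = (i < ps.size()) ? ps[i].start : L;
    int g = next_start - prev_end;
    if (g >= 20) nbind += g - 19;
    if (i < ps.size()) {
      if (ps[i].mode == 20) {
        ++n20;
        int end20 = ps[i].start + 20;
        int ns = (i + 1 < ps.size()) ? ps[i + 1].start : L;
        if (ns - end20 >= 10) ++next_ok;
      } else ++n30;
      prev_end = ps[i].start + ps[i].mode;
    }
  }
  return NumericVector::create(_["bind"] = k1 * nbind, _["unbind"] = km1 * n20,
                               _["extend"] = k2 * next_ok, _["revert"] = km2 * n30);
}
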