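// First-reaction Gillespie core for the multi-gene random telegraph model,
// optionally extended with an expression-dependent commitment hazard.
//
// Uses R's RNG (via RNGScope) so that set.seed() in R governs all draws.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// exponential waiting time with given mean; infinite mean = action never fires
inline double rexp_mean(double mean) {
  if (!R_finite(mean)) return R_PosInf;
  return R::exp_rand() * mean;
}

// measured expression scale: g = delta + log2(m) for m >= 1, floored at 0;
// m = 0 is undetected and coded as g = 0
inline double g_of_m(int m, double delta) {
  if (m < 1) return 0.0;
  double g = delta + std::log2(static_cast<double>(m));
  return g > 0.0 ? g : 0.0;
}

struct Picked {
  double dt;
  int gene;    // 0-based gene index, -1 for the commitment channel
  int action;  // 0 activate, 1 repress, 2 produce, 3 decay, 4 commit
};

// Draw fresh waiting times for every possible action and select the minimum.
// Aggregate decay: one clock with mean tau_dec / m (superposition of m
// per-molecule clocks).
Picked pick_action(const std::vector<int>& s, const std::vector<int>& m,
                   const NumericVector& tau_act, const NumericVector& tau_rep,
                   const NumericVector& tau_prod, const NumericVector& tau_dec,
                   bool with_commit, double lambda) {
  Picked best;
  best.dt = R_PosInf;
  best.gene = -2;
  best.action = -1;
  const int n = static_cast<int>(s.size());
  for (int i = 0; i < n; ++i) {
    if (s[i] == 0) {
      double t = rexp_mean(tau_act[i]);
      if (t < best.dt) { best.dt = t; best.gene = i; best.action = 0; }
    } else {
      double t = rexp_mean(tau_rep[i]);
      if (t < best.dt) { best.dt = t; best.gene = i; best.action = 1; }
      t = rexp_mean(tau_prod[i]);
      if (t < best.dt) { best.dt = t; best.gene = i; best.action = 2; }
    }
    if (m[i] > 0) {
      double t = rexp_mean(tau_dec[i] / m[i]);
      if (t < best.dt) { best.dt = t; best.gene = i; best.action = 3; }
    }
  }
  if (with_commit && lambda > 0.0 && R_finite(lambda)) {
    double t = R::exp_rand() / lambda;
    if (t < best.dt) { best.dt = t; best.gene = -1; best.action = 4; }
  }
  return best;
}

void reset_cell(std::vector<int>& s, std::vector<int>& m,
                const NumericVector& tau_act, const NumericVector& tau_rep) {
  const int n = static_cast<int>(s.size());
  for (int i = 0; i < n; ++i) {
    m[i] = 0;
    if (!R_finite(tau_rep[i])) {
      s[i] = 1;  // locked ON
    } else {
      s[i] = 0;  // default start OFF (also covers locked OFF)
    }
  }
}

// Run the event loop off-clock until every non-exempt gene has executed at
// least one activation and one repression.
void thermalize_state(std::vector<int>& s, std::vector<int>& m,
                      const NumericVector& tau_act, const NumericVector& tau_rep,
                      const NumericVector& tau_prod, const NumericVector& tau_dec,
                      const LogicalVector& exempt,
                      std::vector<int>& n_act, std::vector<int>& n_rep) {
  const int n = static_cast<int>(s.size());
  for (int i = 0; i < n; ++i) {
    if (!exempt[i] && (!R_finite(tau_act[i]) || !R_finite(tau_rep[i]))) {
      stop("gene %d blocks thermalization: locked promoter cannot complete an ON/OFF cycle (waive via therm_exempt)",
           i + 1);
    }
  }
  std::fill(n_act.begin(), n_act.end(), 0);
  std::fill(n_rep.begin(), n_rep.end(), 0);
  auto done = [&]() {
    for (int i = 0; i < n; ++i) {
      if (!exempt[i] && (n_act[i] < 1 || n_rep[i] < 1)) return false;
    }
    return true;
  };
  long guard = 0;
  const long guard_max = 100000000L;
  while (!done()) {
    Picked pk = pick_action(s, m, tau_act, tau_rep, tau_prod, tau_dec, false, 0.0);
    if (!R_finite(pk.dt)) {
      stop("simulation stalled during thermalization: no possible actions");
    }
    const int i = pk.gene;
    switch (pk.action) {
      case 0: s[i] = 1; ++n_act[i]; break;
      case 1: s[i] = 0; ++n_rep[i]; break;
      case 2: m[i] += 1; break;
      case 3: m[i] -= 1; break;
    }
    if (++guard > guard_max) stop("thermalization event budget exceeded");
  }
}

}  // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector tau_act, NumericVector tau_rep,
              NumericVector tau_prod, NumericVector tau_dec,
              NumericVector delta,
              double duration,
              IntegerVector s_init, IntegerVector m_init,
              bool do_therm, LogicalVector therm_exempt,
              bool record_events,
              bool with_commit, double beta0, NumericVector beta,
              double rate_scale, bool restart_on_commit,
              bool track_prob) {
  const int n = tau_act.size();
  std::vector<int> s(n), m(n);
  for (int i = 0; i < n; ++i) {
    s[i] = s_init[i];
    m[i] = m_init[i];
  }
  std::vector<int> therm_act(n, 0), therm_rep(n, 0);
  if (do_therm) {
    thermalize_state(s, m, tau_act, tau_rep, tau_prod, tau_dec, therm_exempt,
                     therm_act, therm_rep);
  }
  IntegerVector s0(n), m0(n);
  for (int i = 0; i < n; ++i) { s0[i] = s[i]; m0[i] = m[i]; }

  std::vector< std::vector<double> > occ(n);
  for (int i = 0; i < n; ++i) occ[i].assign(m[i] + 1, 0.0);

  std::vector<double> ev_time;
  std::vector<int> ev_gene, ev_action, ev_m, ev_s;
  std::vector<double> com_time, com_prob;
  std::vector<int> com_m, com_s;  // row-major: one row of n genes per event

  const bool need_prob = with_commit || track_prob;
  double t = 0.0;
  double t_end = duration;
  double prob_int = 0.0;
  long guard = 0;
  const long guard_max = 500000000L;

  while (t < duration) {
    double p = 0.0, lambda = 0.0;
    if (need_prob) {
      double z = beta0;
      for (int i = 0; i < n; ++i) z += beta[i] * g_of_m(m[i], delta[i]);
      p = 1.0 / (1.0 + std::exp(-z));
      lambda = rate_scale * p;
    }
    Picked pk = pick_action(s, m, tau_act, tau_rep, tau_prod, tau_dec,
                            with_commit, lambda);
    // no possible action: the state is frozen (e.g. all promoters locked
    // OFF with no mRNA) and simply sits out the remaining time
    const bool clipped = !R_finite(pk.dt) || (t + pk.dt >= duration);
    const double dt_eff = clipped ? (duration - t) : pk.dt;
    for (int i = 0; i < n; ++i) {
      if (static_cast<int>(occ[i].size()) <= m[i]) occ[i].resize(m[i] + 1, 0.0);
      occ[i][m[i]] += dt_eff;
    }
    if (need_prob) prob_int += p * dt_eff;
    if (clipped) { t = duration; break; }
    t += pk.dt;

    if (pk.action == 4) {
      // snapshot of the state immediately before the commit event
      com_time.push_back(t);
      com_prob.push_back(p);
      for (int i = 0; i < n; ++i) { com_m.push_back(m[i]); com_s.push_back(s[i]); }
      if (record_events) {
        ev_time.push_back(t);
        ev_gene.push_back(NA_INTEGER);
        ev_action.push_back(4);
        ev_m.push_back(NA_INTEGER);
        ev_s.push_back(NA_INTEGER);
      }
      if (!restart_on_commit) {
        t_end = t;  // absorbing mode: the run ends at the commitment event
        break;
      }
      // a fresh thermalized cell continues the time-course on the same clock
      reset_cell(s, m, tau_act, tau_rep);
      if (do_therm) {
        thermalize_state(s, m, tau_act, tau_rep, tau_prod, tau_dec, therm_exempt,
                         therm_act, therm_rep);
      }
    } else {
      const int i = pk.gene;
      switch (pk.action) {
        case 0: s[i] = 1; break;
        case 1: s[i] = 0; break;
        case 2: m[i] += 1; break;
        case 3: m[i] -= 1; break;
      }
      if (record_events) {
        ev_time.push_back(t);
        ev_gene.push_back(i + 1);
        ev_action.push_back(pk.action);
        ev_m.push_back(m[i]);
        ev_s.push_back(s[i]);
      }
    }
    if (++guard > guard_max) stop("event budget exceeded");
  }

  List occ_out(n);
  for (int i = 0; i < n; ++i) occ_out[i] = NumericVector(occ[i].begin(), occ[i].end());

  const int k = static_cast<int>(com_time.size());
  IntegerMatrix com_m_mat(k, n), com_s_mat(k, n);
  for (int r = 0; r < k; ++r) {
    for (int i = 0; i < n; ++i) {
      com_m_mat(r, i) = com_m[r * n + i];
      com_s_mat(r, i) = com_s[r * n + i];
    }
  }

  IntegerVector s_fin(n), m_fin(n);
  for (int i = 0; i < n; ++i) { s_fin[i] = s[i]; m_fin[i] = m[i]; }

  return List::create(
      _["s0"] = s0, _["m0"] = m0,
      _["s"] = s_fin, _["m"] = m_fin,
      _["t_end"] = t_end,
      _["occupancy"] = occ_out,
      _["prob_integral"] = prob_int,
      _["ev_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["ev_gene"] = IntegerVector(ev_gene.begin(), ev_gene.end()),
      _["ev_action"] = IntegerVector(ev_action.begin(), ev_action.end()),
      _["ev_m"] = IntegerVector(ev_m.begin(), ev_m.end()),
      _["ev_s"] = IntegerVector(ev_s.begin(), ev_s.end()),
      _["commit_time"] = NumericVector(com_time.begin(), com_time.end()),
      _["commit_prob"] = NumericVector(com_prob.begin(), com_prob.end()),
      _["commit_m"] = com_m_mat,
      _["commit_s"] = com_s_mat,
      _["therm_act"] = IntegerVector(therm_act.begin(), therm_act.end()),
      _["therm_rep"] = IntegerVector(therm_rep.begin(), therm_rep.end()));
}
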