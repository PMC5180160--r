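#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Learning-rate lookup: alpha_v may be a scalar, an (obs x behaviour) matrix
// flattened column-major, or an (obs x behaviour x next-obs) array.
static inline double lookup_av(const NumericVector &av, int n_o, int n_b,
                               int o, int c, int o2) {
  if (av.size() == 1) return av[0];
  if (av.size() == n_o * n_b) return av[o + n_o * c];
  return av[o + n_o * (c + n_b * o2)];
}

static inline double lookup_aw(const NumericVector &aw, int n_o,
                               int o, int o2) {
  if (aw.size() == 1) return aw[0];
  if (aw.size() == n_o) return aw[o];
  return aw[o + n_o * o2];
}

// Core attempt loop. RNG draws (one uniform per entry with >1 candidate
// states, one per behaviour choice, one per stochastic kernel edge) and all
// accumulations (long double, stored back to double element-wise) mirror the
// pure-R reference engine exactly, so both engines are bit-identical on the
// same seed.
// [[Rcpp::export]]
List cpp_run_attempts(int n_attempts,
                      IntegerVector obs_of,
                      NumericVector u,
                      LogicalVector terminal,
                      LogicalVector reward_state,
                      int start_state,
                      IntegerVector entry_states,
                      NumericVector entry_cum,
                      List rep_cols,
                      List kern_ns,
                      List kern_cp,
                      NumericMatrix V,
                      NumericVector W,
                      NumericMatrix Beta,
                      NumericMatrix Mod,
                      LogicalVector has_mod_row,
                      LogicalVector terminal_obs,
                      NumericVector alpha_v,
                      NumericVector alpha_w,
                      bool chaining,
                      int max_steps,
                      int reset_mode, // 0 none, 1 any return, 2 arrival only
                      bool record,
                      int attempt_offset) {
  const int n_o = V.nrow();
  const int n_b = V.ncol();
  const int n_entry = entry_states.size();

  std::vector<int> a_entry, a_steps, a_ended, a_highest;
  std::vector<double> a_total;
  std::vector<int> a_reached;
  a_entry.reserve(n_attempts); a_steps.reserve(n_attempts);
  a_ended.reserve(n_attempts); a_highest.reserve(n_attempts);
  a_total.reserve(n_attempts); a_reached.reserve(n_attempts);

  std::vector<int> t_attempt, t_step, t_state, t_beh, t_next;
  std::vector<double> t_u, t_dv;
  std::vector<int> t_term;

  std::vector<double> sc(64), pe(64);

  for (int a = 0; a < n_attempts; ++a) {
    // entry draw
    int s;
    if (n_entry > 1) {
      double r = unif_rand();
      int i = 0;
      while (i < n_entry - 1 && r > entry_cum[i]) ++i;
      s = entry_states[i] - 1;
    } else {
      s = entry_states[0] - 1;
    }
    a_entry.push_back(s + 1);

    bool has_dv = false;
    double dv = 0.0;
    int steps = 0, ended = 0, highest = s;
    double tot = 0.0;
    bool reached = false;

    while (true) {
      if (steps >= max_steps) { ended = 3; break; }
      int o = obs_of[s] - 1;
      IntegerVector cols = rep_cols[s];
      int k = cols.size();
      if ((int)sc.size() < k) { sc.resize(k); pe.resize(k); }

      // softmax scores with per-pair beta and prediction-error modulation
      double mx = R_NegInf;
      for (int i = 0; i < k; ++i) {
        int c = cols[i] - 1;
        double b = Beta(o, c);
        if (has_mod_row[o]) {
          double m0 = Mod(o, c);
          if (!ISNA(m0)) b = m0 - (has_dv ? dv : 0.0);
        }
        sc[i] = b * V(o, c);
        if (sc[i] > mx) mx = sc[i];
      }
      long double sum = 0.0L;
      for (int i = 0; i < k; ++i) { pe[i] = std::exp(sc[i] - mx); sum += pe[i]; }
      double S = (double)sum;

      // behaviour draw (first index whose cumulative prob >= r)
      double r = unif_rand();
      int j = k - 1;
      long double acc = 0.0L;
      for (int i = 0; i < k; ++i) {
        acc += pe[i] / S;
        double ci = (double)acc;
        if (r <= ci) { j = i; break; }
      }

      // kernel draw
      List kns = kern_ns[s];
      IntegerVector ns = kns[j];
      int s2;
      if (ns.size() > 1) {
        List kcp = kern_cp[s];
        NumericVector cp = kcp[j];
        double r2 = unif_rand();
        int i = 0;
        while (i < ns.size() - 1 && r2 > cp[i]) ++i;
        s2 = ns[i] - 1;
      } else {
        s2 = ns[0] - 1;
      }

      int o2 = obs_of[s2] - 1;
      double u2 = u[s2];
      bool term = terminal[s2];
      // attempt-ending transitions (terminal entry or reset to the start
      // state) are episode boundaries: the update targets bootstrap from 0,
      // while u2 is still collected
      bool reset = s2 == start_state - 1 &&
        (reset_mode == 1 || (reset_mode == 2 && s != s2));
      bool boundary = term || reset;
      double wn = (boundary || !chaining) ? 0.0 : W[o2];
      int c = cols[j] - 1;
      double newdv = u2 + wn - V(o, c);
      double wtarg = u2 + wn - W[o];

      V(o, c) += lookup_av(alpha_v, n_o, n_b, o, c, o2) * newdv;
      if (chaining && !terminal_obs[o])
        W[o] += lookup_aw(alpha_w, n_o, o, o2) * wtarg;

      tot += u2;
      if (reward_state[s2]) reached = true;
      if (s2 > highest) highest = s2;
      ++steps;

      if (record) {
        t_attempt.push_back(attempt_offset + a + 1);
        t_step.push_back(steps);
        t_state.push_back(s + 1);
        t_beh.push_back(c + 1);
        t_next.push_back(s2 + 1);
        t_u.push_back(u2);
        t_dv.push_back(newdv);
        t_term.push_back(term ? 1 : 0);
      }

      dv = newdv; has_dv = true;

      if (term) { ended = 1; break; }
      if (reset) { ended = 2; break; }
      s = s2;
    }

    a_steps.push_back(steps);
    a_ended.push_back(ended);
    a_highest.push_back(highest + 1);
    a_total.push_back(tot);
    a_reached.push_back(reached ? 1 : 0);
  }

  List out = List::create(
    _["entry"] = wrap(a_entry),
    _["steps"] = wrap(a_steps),
    _["total_u"] = wrap(a_total),
    _["reached"] = wrap(a_reached),
    _["ended"] = wrap(a_ended),
    _["highest"] = wrap(a_highest));
  if (record) {
    out["tr_attempt"] = wrap(t_attempt);
    out["tr_step"] = wrap(t_step);
    out["tr_state"] = wrap(t_state);
    out["tr_beh"] = wrap(t_beh);
    out["tr_next"] = wrap(t_next);
    out["tr_u"] = wrap(t_u);
    out["tr_dv"] = wrap(t_dv);
    out["tr_term"] = wrap(t_term);
  }
  return out;
}
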