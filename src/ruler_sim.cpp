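#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-constant ruler rates as a function of the gap d between a
// nucleosome flank and the nearest obstacle edge on that side.
// mode: 0 = reciprocal, 1 = asymmetric, 2 = kinetic_release.
static inline void ruler_rates_cpp(double d, double a, double b, double r0,
                                   double beta, int mode, double gamma,
                                   double &toward, double &away) {
  const double BIG = 1e17;
  if (d >= BIG) { toward = r0; away = r0; return; }  // no obstacle: region C
  if (d < a) {
    toward = r0 * (1.0 - beta);
    away = (mode == 1) ? r0 : r0 * (1.0 + beta);
  } else if (d < a + b) {
    toward = r0 * (1.0 + beta);
    away = (mode == 1) ? r0 : r0 * (1.0 - beta);
  } else {
    toward = r0;
    away = r0;
  }
  if (mode == 2 && d == a) {  // kinetic release: total-rate minimum at d = a
    toward *= (1.0 - gamma);
    away *= (1.0 - gamma);
  }
}

// [[Rcpp::export]]
List ruler_sim_cpp(double L, int hw, IntegerVector pos0,
                   NumericVector barrier_lo, NumericVector barrier_hi,
                   double a, double b, double r0, double beta, int mode,
                   double gamma, double t_max, double burn_in,
                   double max_events) {
  const double BIG = 1e18;
  int N = pos0.size(), nb = barrier_lo.size();
  std::vector<double> pos(N);
  for (int i = 0; i < N; ++i) pos[i] = pos0[i];
  int Li = (int)L;
  NumericVector occ(Li);
  std::vector<double> rateL(N), rateR(N);

  double t = 0.0;
  double n_events = 0.0;
  bool jammed = false;

  while (t < t_max && n_events < max_events) {
    // gaps and rates for every nucleosome (N is small: recompute each event)
    double total = 0.0;
    for (int i = 0; i < N; ++i) {
      double f = pos[i] - hw;        // leftmost occupied base
      double g = pos[i] + hw + 1;    // one past rightmost occupied base
      // nearest ruler obstacle on each side (neighbor beats barrier)
      double dL = BIG, dR = BIG;
      if (i > 0) dL = f - (pos[i - 1] + hw + 1);
      for (int j = 0; j < nb; ++j)
        if (barrier_hi[j] <= f) dL = std::min(dL, f - barrier_hi[j]);
      if (i < N - 1) dR = (pos[i + 1] - hw) - g;
      for (int j = 0; j < nb; ++j)
        if (barrier_lo[j] >= g) dR = std::min(dR, barrier_lo[j] - g);
      // hard-core blocking: obstacles and the domain walls at 0 and L
      bool okL = (f >= 1.0) && (dL >= BIG || dL >= 1.0);
      bool okR = (g <= L - 1.0) && (dR >= BIG || dR >= 1.0);
      double twL, awL, twR, awR;
      ruler_rates_cpp(dL, a, b, r0, beta, mode, gamma, twL, awL);
      ruler_rates_cpp(dR, a, b, r0, beta, mode, gamma, twR, awR);
      // each side's gap contributes an independent multiplicative factor
      rateL[i] = okL ? twL * awR / r0 : 0.0;
      rateR[i] = okR ? twR * awL / r0 : 0.0;
      total += rateL[i] + rateR[i];
    }
    double t_next;
    if (total <= 0.0) {
      jammed = true;
      if (!R_finite(t_max)) break;  // fully blocked, nothing to average over
      t_next = t_max;
    } else t_next = t + exp_rand() / total;

    // time-weighted occupancy over [t, t_next) after burn-in
    double lo = std::max(t, burn_in);
    double hi = std::min(t_next, t_max);
    if (hi > lo) {
      double w = hi - lo;
      for (int i = 0; i < N; ++i) occ[(int)pos[i]] += w;
    }
    if (jammed || t_next >= t_max) { t = std::min(t_next, t_max); break; }

    // pick the event
    double u = unif_rand() * total, acc = 0.0;
    int which = -1, dir = 0;
    for (int i = 0; i < N && which < 0; ++i) {
      acc += rateL[i];
      if (u < acc) { which = i; dir = -1; break; }
      acc += rateR[i];
      if (u < acc) { which = i; dir = +1; break; }
    }
    if (which < 0) { which = N - 1; dir = (rateR[N - 1] > 0) ? +1 : -1; }
    pos[which] += dir;
    t = t_next;
    n_events += 1.0;
  }

  IntegerVector final_pos(N);
  for (int i = 0; i < N; ++i) final_pos[i] = (int)pos[i];
  return List::create(_["occ"] = occ, _["t_end"] = t,
                      _["n_events"] = n_events, _["final_pos"] = final_pos,
                      _["jammed"] = jammed);
}
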