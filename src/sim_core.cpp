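#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time conditionally-Bernoulli spike-train simulator.
//
// At each 1-ms step an electrode fires with probability
//   p_i(t) = base_prob_i * gain(t) + sum_j W[j,i] * fired[j, t-1]
// clipped to [0, 1 - 1e-6].  gain(t) = burst_gain while the well-global
// two-state burst process is in its "on" state, else 1.  The burst process
// is a Markov chain with per-step transition probabilities p_on (off->on)
// and p_off (on->off).  Uses R's RNG so set.seed() governs reproducibility.
//
// Returns spike (electrode, step) pairs, the per-step burst state, and the
// number of probability clips that occurred.
// [[Rcpp::export]]
List sim_spike_core(int n_steps, NumericVector base_prob, NumericMatrix W,
                    bool has_coupling, double p_on, double p_off,
                    double burst_gain) {
  const int n_e = base_prob.size();
  const double p_max = 1.0 - 1e-6;

  std::vector<int> sp_elec, sp_step;
  sp_elec.reserve(4096);
  sp_step.reserve(4096);
  LogicalVector burst_state(n_steps);

  std::vector<int> prev_fired;   // electrodes that fired at t-1
  std::vector<double> p_extra(n_e, 0.0);
  bool burst_on = false;
  long clipped = 0;

  for (int t = 0; t < n_steps; ++t) {
    // well-global burst state update
    double u = unif_rand();
    if (burst_on) {
      if (u < p_off) burst_on = false;
    } else {
      if (u < p_on) burst_on = true;
    }
    burst_state[t] = burst_on;
    const double gain = burst_on ? burst_gain : 1.0;

    if (has_coupling) {
      std::fill(p_extra.begin(), p_extra.end(), 0.0);
      for (size_t k = 0; k < prev_fired.size(); ++k) {
        const int j = prev_fired[k];
        for (int i = 0; i < n_e; ++i) p_extra[i] += W(j, i);
      }
    }

    std::vector<int> fired_now;
    for (int i = 0; i < n_e; ++i) {
      double p = base_prob[i] * gain;
      if (has_coupling) p += p_extra[i];
      if (p > p_max) { p = p_max; ++clipped; }
      if (unif_rand() < p) {
        sp_elec.push_back(i + 1);
        sp_step.push_back(t);
        fired_now.push_back(i);
      }
    }
    prev_fired.swap(fired_now);
  }

  return List::create(_["electrode"] = wrap(sp_elec),
                      _["step"] = wrap(sp_step),
                      _["burst_state"] = burst_state,
                      _["n_clipped"] = (double)clipped);
}

// Second-order-section (biquad cascade) causal filter.  sos is k x 6:
// [b0 b1 b2 a0 a1 a2] per row, a0 == 1.  Direct form II transposed.
// steady_init initializes each section's state to its step-response steady
// state for the first input sample, suppressing startup transients (and
// making a constant input map to a constant output exactly).
// [[Rcpp::export]]
NumericVector sosfilt_core(NumericMatrix sos, NumericVector x,
                           bool steady_init) {
  const int n = x.size(), k = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = 0.0, w2 = 0.0;
    if (steady_init && n > 0) {
      const double x0 = y[0];
      const double g = (b0 + b1 + b2) / (1.0 + a1 + a2);
      const double y0 = g * x0;
      w2 = b2 * x0 - a2 * y0;
      w1 = b1 * x0 - a1 * y0 + w2;
    }
    for (int t = 0; t < n; ++t) {
      const double xt = y[t];
      const double yt = b0 * xt + w1;
      w1 = b1 * xt - a1 * yt + w2;
      w2 = b2 * xt - a2 * yt;
      y[t] = yt;
    }
  }
  return y;
}
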