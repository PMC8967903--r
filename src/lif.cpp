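#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of a leaky integrate-and-fire neuron.
// Units: V in mV, t in ms, C in pF, g in nS, I in pA (so I/C and g*dV/C are mV/ms).
// Reset-to-E_l on threshold crossing; additive Gaussian voltage noise per step.
// Uses R's RNG (norm_rand) so results are reproducible under set.seed().

// [[Rcpp::export]]
List lif_sim_cpp(NumericVector current_pA, double dt, double C_m, double g_l,
                 double E_l, double V_thresh, double V_init, double sigma_step,
                 bool return_voltage) {
  int n = current_pA.size();
  NumericVector V_out(return_voltage ? n : 0);
  std::vector<int> spikes;
  double V = V_init;
  for (int k = 0; k < n; ++k) {
    double eta = (sigma_step > 0.0) ? norm_rand() * sigma_step : 0.0;
    V += dt * (current_pA[k] - g_l * (V - E_l)) / C_m + eta;
    if (!R_finite(V)) stop("membrane voltage diverged; reduce dt");
    if (V > V_thresh) {
      V = E_l;
      spikes.push_back(k + 1);  // 1-based step index of the spike
    }
    if (return_voltage) V_out[k] = V;
  }
  return List::create(_["spike_count"] = (int)spikes.size(),
                      _["spike_steps"] = wrap(spikes),
                      _["voltage"]     = V_out);
}

// Batch of independent trials with constant current per trial (spike counts only).
// [[Rcpp::export]]
IntegerVector lif_counts_cpp(NumericVector currents_pA, int n_steps, double dt,
                             double C_m, double g_l, double E_l, double V_thresh,
                             double V_init, double sigma_step) {
  int ntr = currents_pA.size();
  IntegerVector out(ntr);
  for (int t = 0; t < ntr; ++t) {
    double V = V_init, I = currents_pA[t];
    int c = 0;
    for (int k = 0; k < n_steps; ++k) {
      double eta = (sigma_step > 0.0) ? norm_rand() * sigma_step : 0.0;
      V += dt * (I - g_l * (V - E_l)) / C_m + eta;
      if (!R_finite(V)) stop("membrane voltage diverged; reduce dt");
      if (V > V_thresh) { V = E_l; ++c; }
    }
    out[t] = c;
  }
  return out;
}
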