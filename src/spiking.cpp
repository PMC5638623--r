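#include <Rcpp.h>
using namespace Rcpp;

// Core loop of the stochastic spiking simulator.
//
// Input spike trains are inhomogeneous Poisson processes whose rates are
// piecewise constant over trajectory updates (zero-order hold); within a
// neural time step dt at most one spike per channel is drawn (Bernoulli
// approximation, error O((r dt)^2)). The adaptation integral of the output
// rate is maintained by two exact exponential traces per synapse (one per
// kernel component), and all-to-all STDP pairing by exponential pre/post
// traces, which is exact for the exponential learning window.
//
// rates:     n_updates x N matrix of input rates (Hz), one row per
//            trajectory update (held for `hold` neural steps each)
// w:         initial weights (modified copy returned via checkpoints)
// order per step: decay STDP traces; draw input spikes; update kernel
// traces; compute rectified output rate; draw output spike; apply Hebbian
// pairing, then per-pre-spike normalization, then clamp at 0; add the new
// spikes to the STDP traces.
// [[Rcpp::export(name = ".spikingCore")]]
List spikingCore(NumericMatrix rates, NumericVector w_init,
                 double dt, int hold,
                 double tau_s, double tau_l, double mu,
                 double r0, double eta, double tau_w, double w_tot,
                 double alpha, double beta,
                 IntegerVector checkpoint_steps,
                 bool record_spikes) {
  const int n_upd = rates.nrow(), N = rates.ncol();
  const int n_steps = n_upd * hold;
  const double dS = std::exp(-dt / tau_s), dL = std::exp(-dt / tau_l);
  const double dW = std::exp(-dt / tau_w);
  const double cS = 1.0 / tau_s, cL = mu / tau_l;
  const double W0 = w_tot / (2.0 * tau_w);

  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> xS(N, 0.0), xL(N, 0.0), pre(N, 0.0);
  double post = 0.0;
  std::vector<int> spk(N, 0);

  NumericMatrix w_hist(checkpoint_steps.size(), N);
  int next_cp = 0;
  long n_out_spikes = 0, n_in_spikes = 0;
  std::vector<double> out_spike_t;

  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    const int row = step / hold;
    // 1. decay STDP traces to the current bin
    post *= dW;
    for (int i = 0; i < N; ++i) pre[i] *= dW;
    // 2. input spikes (Bernoulli(rate*dt)) + kernel traces
    double drive = 0.0;
    for (int i = 0; i < N; ++i) {
      spk[i] = (unif_rand() < rates(row, i) * dt) ? 1 : 0;
      n_in_spikes += spk[i];
      xS[i] = xS[i] * dS + spk[i];
      xL[i] = xL[i] * dL + spk[i];
      drive += w[i] * (cS * xS[i] - cL * xL[i]);
    }
    // 3. output rate, rectified, and output spike
    double rout = r0 + drive;
    if (rout < 0) rout = 0;
    const int out = (unif_rand() < rout * dt) ? 1 : 0;
    if (out) {
      ++n_out_spikes;
      if (record_spikes) out_spike_t.push_back((step + 1) * dt);
    }
    // 4. plasticity: Hebbian pairing, then normalization, then clamp
    if (eta != 0.0) {
      for (int i = 0; i < N; ++i) {
        double dwi = 0.0;
        if (spk[i]) dwi += eta * W0 * (post + out);  // pre with past+current post
        if (out)    dwi += eta * W0 * pre[i];        // post with past pres
        w[i] += dwi;
        if (spk[i]) w[i] += eta * (beta - alpha * w[i]);
        if (w[i] < 0) w[i] = 0;
      }
    }
    // 5. register the new spikes in the STDP traces
    for (int i = 0; i < N; ++i) pre[i] += spk[i];
    post += out;
    // checkpoints are 1-based step counts
    while (next_cp < checkpoint_steps.size() &&
           checkpoint_steps[next_cp] == step + 1) {
      for (int i = 0; i < N; ++i) w_hist(next_cp, i) = w[i];
      ++next_cp;
    }
  }
  return List::create(_["w_hist"] = w_hist,
                      _["n_out_spikes"] = (double)n_out_spikes,
                      _["n_in_spikes"] = (double)n_in_spikes,
                      _["out_spike_times"] = wrap(out_spike_t));
}
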