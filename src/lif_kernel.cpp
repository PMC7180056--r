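#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire network with exact integration of the leak.
// Per step: V <- V * exp(-dt/tau_m), then add the recurrent jumps caused by
// spikes emitted in the PREVIOUS step (spike propagation takes one
// simulation step, making the update independent of neuron ordering), then
// add external Poisson jumps of size j_ext at the per-neuron rate of the
// current schedule window. Neurons at or above threshold emit a spike and
// reset. External event counts are drawn with R's RNG (neuron-major order
// within each step) so runs are reproducible under set.seed().
//
// W:        n x n weight matrix in mV (rows post, cols pre)
// ext_rate: n x n_win matrix of external Poisson rates in events/ms
// breaks:   window boundaries in ms, length n_win + 1 (breaks[0] == 0,
//           breaks[n_win] == t_end)
// [[Rcpp::export]]
List lif_kernel(const NumericMatrix& W, const NumericVector& v0,
                const NumericMatrix& ext_rate, const NumericVector& breaks,
                double tau_m, double v_th, double v_reset, double j_ext,
                double dt) {
  const int n = W.nrow();
  if (W.ncol() != n || v0.size() != n || ext_rate.nrow() != n)
    stop("inconsistent dimensions");
  const int n_win = ext_rate.ncol();
  if (breaks.size() != n_win + 1) stop("breaks must have n_win + 1 entries");
  const double t_end = breaks[n_win];
  const long n_steps = (long)(t_end / dt + 0.5);
  const double decay = std::exp(-dt / tau_m);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<int> spiked_prev;
  std::vector<int> spiked_now;
  std::vector<int> rec_neuron;
  std::vector<double> rec_time;
  rec_neuron.reserve(1 << 16);
  rec_time.reserve(1 << 16);

  int win = 0;
  for (long step = 0; step < n_steps; ++step) {
    const double t_now = step * dt;
    while (win < n_win - 1 && t_now >= breaks[win + 1]) ++win;
    // leak (exact integration between events)
    for (int i = 0; i < n; ++i) v[i] *= decay;
    // recurrent input from spikes of the previous step
    for (size_t k = 0; k < spiked_prev.size(); ++k) {
      const int j = spiked_prev[k];
      const double* col = &W(0, j);
      for (int i = 0; i < n; ++i) v[i] += col[i];
    }
    // external Poisson events
    for (int i = 0; i < n; ++i) {
      const double lam = ext_rate(i, win) * dt;
      if (lam > 0) {
        const double k = R::rpois(lam);
        if (k > 0) v[i] += j_ext * k;
      }
    }
    // threshold and reset
    spiked_now.clear();
    const double t_spike = t_now + dt;
    for (int i = 0; i < n; ++i) {
      if (v[i] >= v_th) {
        v[i] = v_reset;
        spiked_now.push_back(i);
        rec_neuron.push_back(i + 1);
        rec_time.push_back(t_spike);
      }
    }
    spiked_prev.swap(spiked_now);
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["neuron"] = IntegerVector(rec_neuron.begin(), rec_neuron.end()),
    _["time"] = NumericVector(rec_time.begin(), rec_time.end()),
    _["v_final"] = NumericVector(v.begin(), v.end()));
}
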