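#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimal binary min-heap over (time, input) pairs; per-neuron event queue.
struct EventHeap {
  std::vector<double> t;
  std::vector<int> id;
  size_t n = 0;
  void init(size_t cap) { t.assign(cap, 0.0); id.assign(cap, 0); n = 0; }
  void push(double tt, int ii) {
    size_t i = n++;
    t[i] = tt; id[i] = ii;
    while (i > 0) {
      size_t p = (i - 1) >> 1;
      if (t[p] <= t[i]) break;
      std::swap(t[p], t[i]); std::swap(id[p], id[i]); i = p;
    }
  }
  void replace_top(double tt, int ii) {  // pop + push fused
    t[0] = tt; id[0] = ii;
    size_t i = 0;
    for (;;) {
      size_t l = 2 * i + 1, r = l + 1, m = i;
      if (l < n && t[l] < t[m]) m = l;
      if (r < n && t[r] < t[m]) m = r;
      if (m == i) break;
      std::swap(t[m], t[i]); std::swap(id[m], id[i]); i = m;
    }
  }
};

// Population simulation of synaptic weight dynamics.
//
// Each of n_neurons leaky integrate-and-fire neurons receives n_inputs
// synapses. The LIF + STDP part is integrated event-exactly: the membrane
// potential decays exponentially between presynaptic events and is
// incremented by k_gain * w at each event, so there is no time-step error in
// the spiking dynamics. The slow intrinsic noise (multiplicative Kesten +
// additive, Euler-Maruyama) and uniform heterosynaptic scaling are applied on
// a coarse grid of width dt_noise. STDP uses nearest-neighbour pairing with
// exponential window tau_stdp: a postsynaptic spike potentiates each input by
// c_p * exp(-dt/tau) against its most recent presynaptic spike (additive); a
// presynaptic spike depresses its synapse by w * c_d * exp(-dt/tau) against
// the most recent postsynaptic spike (multiplicative).
//
// protocol: 0 silent, 1 Poisson, 2 periodic. Uses R's RNG (seed via set.seed).
// [[Rcpp::export]]
List sim_core(NumericMatrix W0, int protocol, double rate,
              double stim_proportion, double duration, double dt_noise,
              double mult, double add, bool stdp_on, double c_p, double c_d,
              double tau_stdp, double tau_m, double theta, double k_gain,
              bool scaling_on, IntegerVector snap_steps) {
  const int n_neurons = W0.nrow(), n_inputs = W0.ncol();
  const int n_steps = (int)std::lround(duration / dt_noise);
  const double sqdt = std::sqrt(dt_noise);
  const double stdp_window = 10.0 * tau_stdp;  // beyond this, kernel ~ 0
  const int stim_count =
      (protocol == 0) ? 0 : (int)std::floor(stim_proportion * n_inputs);
  const double isi = (rate > 0) ? 1.0 / rate : 0.0;

  NumericMatrix W = clone(W0);
  IntegerVector spikes(n_neurons);
  const int n_snap = snap_steps.size();
  NumericMatrix snaps(n_snap, n_neurons * n_inputs);

  RNGScope scope;
  std::vector<double> w(n_inputs), lastpre(n_inputs);
  EventHeap heap;
  heap.init(stim_count > 0 ? stim_count : 1);

  for (int n = 0; n < n_neurons; ++n) {
    for (int i = 0; i < n_inputs; ++i) w[i] = W(n, i);
    double target = 0.0;
    for (int i = 0; i < n_inputs; ++i) target += w[i];

    std::fill(lastpre.begin(), lastpre.end(), -1e18);
    double lastpost = -1e18, V = 0.0, tV = 0.0;
    heap.n = 0;
    for (int i = 0; i < stim_count; ++i) {
      double t0 = (protocol == 2) ? unif_rand() * isi : exp_rand() * isi;
      heap.push(t0, i);
    }

    int snap_ptr = 0;
    for (int k = 1; k <= n_steps; ++k) {
      const double t_bound = k * dt_noise;
      // --- event-driven LIF + STDP up to the noise boundary ---
      while (heap.n > 0 && heap.t[0] < t_bound) {
        const double te = heap.t[0];
        const int i = heap.id[0];
        const double tnext =
            te + ((protocol == 2) ? isi : exp_rand() * isi);
        heap.replace_top(tnext, i);
        if (te >= duration) continue;
        if (stdp_on) {
          const double dtp = te - lastpost;
          if (dtp < stdp_window)
            w[i] -= w[i] * c_d * std::exp(-dtp / tau_stdp);
        }
        if (V > 1e-4) V *= std::exp(-(te - tV) / tau_m);
        else V = 0.0;
        tV = te;
        V += k_gain * w[i];
        lastpre[i] = te;
        if (V >= theta) {
          ++spikes[n];
          V = 0.0;
          lastpost = te;
          if (stdp_on) {
            const double tmin = te - stdp_window;
            for (int j = 0; j < n_inputs; ++j)
              if (lastpre[j] > tmin)
                w[j] += c_p * std::exp(-(te - lastpre[j]) / tau_stdp);
          }
        }
      }
      // --- intrinsic noise (Euler-Maruyama) + heterosynaptic scaling ---
      if (mult > 0.0 || add > 0.0) {
        const double am = mult * sqdt, aa = add * sqdt;
        for (int i = 0; i < n_inputs; ++i) {
          double wi = w[i];
          if (mult > 0.0) wi *= 1.0 + am * norm_rand();
          if (add > 0.0) wi += aa * norm_rand();
          w[i] = (wi > 0.0) ? wi : 0.0;
        }
      }
      if (scaling_on) {
        double tot = 0.0;
        for (int i = 0; i < n_inputs; ++i) tot += w[i];
        if (tot > 0.0) {
          const double s = target / tot;
          for (int i = 0; i < n_inputs; ++i) w[i] *= s;
        }
      }
      if (snap_ptr < n_snap && snap_steps[snap_ptr] == k) {
        for (int i = 0; i < n_inputs; ++i)
          snaps(snap_ptr, (R_xlen_t)n * n_inputs + i) = w[i];
        ++snap_ptr;
      }
    }
    for (int i = 0; i < n_inputs; ++i) {
      if (!std::isfinite(w[i]))
        stop("NaN/Inf weight detected (neuron %d, input %d)", n + 1, i + 1);
      W(n, i) = w[i];
    }
  }
  return List::create(_["weights"] = W, _["spike_counts"] = spikes,
                      _["snapshots"] = snaps);
}
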