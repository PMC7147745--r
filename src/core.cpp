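#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete-time core for the conductance-based LIF network with adaptive
// thresholds, OU membrane noise, online nearest-neighbour STDP and incoming
// synaptic normalization. Layout: neurons 0..nE-1 excitatory, nE..n-1
// inhibitory. Weight matrix W is (post x pre): column i holds the outgoing
// weights of presynaptic neuron i, so spike propagation is a contiguous
// column read. All times in ms, conductances in nS, voltages in mV,
// capacitance in pF, currents in pA (nS*mV).

// Incoming E->E normalization of neuron `post`: rescale the row so that the
// sum over the (fixed) adjacency equals w_total. Zero sums are left alone.
static inline void normalize_row(NumericMatrix &W, const LogicalMatrix &adjEE,
                                 int post, int nE, double w_total) {
  double s = 0.0;
  for (int i = 0; i < nE; ++i)
    if (adjEE(post, i)) s += W(post, i);
  if (s > 0.0) {
    double f = w_total / s;
    for (int i = 0; i < nE; ++i)
      if (adjEE(post, i)) W(post, i) *= f;
  }
}

// [[Rcpp::export]]
List sim_core(List state, NumericMatrix W_in, LogicalMatrix adjEE, List par,
              int n_steps, IntegerVector ev_step, IntegerVector ev_neuron,
              NumericVector ev_w, bool plastic, bool record,
              NumericVector I_ext) {
  // deep-copy: the caller's matrix must not be mutated in place
  NumericMatrix W = clone(W_in);
  NumericVector v = clone(as<NumericVector>(state["v"]));
  NumericVector g_ampa = clone(as<NumericVector>(state["g_ampa"]));
  NumericVector g_gaba = clone(as<NumericVector>(state["g_gaba"]));
  NumericVector v_th = clone(as<NumericVector>(state["v_th"]));
  NumericVector refrac_until = clone(as<NumericVector>(state["refrac_until"]));
  NumericVector xi = clone(as<NumericVector>(state["xi"]));
  NumericVector last_spike = clone(as<NumericVector>(state["last_spike"]));
  double t0 = as<double>(state["t"]);

  const int n = v.size();
  const int nE = as<int>(par["n_E"]);
  const double dt = as<double>(par["dt"]);
  const double g_leak = as<double>(par["g_leak"]);
  const double v_rest = as<double>(par["v_rest"]);
  const double c_m = as<double>(par["c_membrane"]);
  const double tau_m = as<double>(par["tau_membrane"]);
  const double tau_ampa = as<double>(par["tau_ampa"]);
  const double tau_gaba = as<double>(par["tau_gaba"]);
  const double e_ampa = as<double>(par["e_ampa"]);
  const double e_gaba = as<double>(par["e_gaba"]);
  const double eta_decay = as<double>(par["eta_decay_ip"]) / 1000.0; // mV/s -> mV/ms
  const double eta_spike = as<double>(par["eta_spike_ip"]);
  const double sigma_noise = as<double>(par["sigma_noise"]);
  const double ou_tau = as<double>(par["ou_tau"]);
  const double refrac_E = as<double>(par["refrac_E"]);
  const double refrac_I = as<double>(par["refrac_I"]);
  const double th_floor = as<double>(par["th_floor"]);
  const bool ip_inhib = as<bool>(par["ip_inhibitory"]);

  const double A_plus = as<double>(par["A_plus"]);
  const double A_minus = as<double>(par["A_minus"]);
  const double tau_plus = as<double>(par["tau_plus"]);
  const double tau_minus = as<double>(par["tau_minus"]);
  const double w_total = as<double>(par["w_total"]);
  const bool normalize = as<bool>(par["normalize"]);

  // The OU generator xi has unit stationary variance and correlation time
  // ou_tau; its drive coefficient is calibrated so that the leak-filtered
  // stationary membrane fluctuation has standard deviation sigma_noise
  // (leak-only voltage time constant tau_v = c_m / g_leak).
  const double tau_v = c_m / g_leak;
  const double noise_k =
      sigma_noise * std::sqrt((ou_tau + tau_v) / ou_tau) / tau_v;

  const double dec_ampa = std::exp(-dt / tau_ampa);
  const double dec_gaba = std::exp(-dt / tau_gaba);
  const double ou_a = ou_tau > 0 ? std::exp(-dt / ou_tau) : 0.0;
  const double ou_b = ou_tau > 0 ? std::sqrt(1.0 - ou_a * ou_a) : 0.0;
  const bool noisy = sigma_noise > 0.0;
  const double NEVER = -1e18;

  std::vector<int> sp_step, sp_neuron;
  std::vector<int> spikers;
  spikers.reserve(64);

  int ev_ptr = 0;
  const int n_ev = ev_step.size();

  RNGScope rng;

  // Marsaglia polar normal draws on top of R's uniform stream: much faster
  // than the default inversion sampler, still fully determined by set.seed.
  double spare = 0.0;
  bool has_spare = false;
  auto fast_norm = [&]() -> double {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, w, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      w = 2.0 * unif_rand() - 1.0;
      s = u * u + w * w;
    } while (s >= 1.0 || s == 0.0);
    const double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = w * m;
    has_spare = true;
    return u * m;
  };

  for (int s = 0; s < n_steps; ++s) {
    const double t_now = t0 + (s + 1) * dt;

    // 1. external input events scheduled for this step (AMPA increments)
    while (ev_ptr < n_ev && ev_step[ev_ptr] == s) {
      g_ampa[ev_neuron[ev_ptr]] += ev_w[ev_ptr];
      ++ev_ptr;
    }

    // 2. integrate membrane + threshold decay
    for (int j = 0; j < n; ++j) {
      if (noisy) xi[j] = ou_a * xi[j] + ou_b * fast_norm();
      if (t_now >= refrac_until[j]) {
        double I = g_leak * (v_rest - v[j]) + g_ampa[j] * (e_ampa - v[j]) +
                   g_gaba[j] * (e_gaba - v[j]) + I_ext[j];
        v[j] += dt * I / c_m;
        if (noisy) v[j] += dt * noise_k * xi[j];
      } else {
        v[j] = v_rest; // clamped during the absolute refractory period
      }
      if (ip_inhib || j < nE) {
        v_th[j] -= eta_decay * dt;
        if (v_th[j] < th_floor) v_th[j] = th_floor;
      }
    }

    // 3. conductance decay
    for (int j = 0; j < n; ++j) {
      g_ampa[j] *= dec_ampa;
      g_gaba[j] *= dec_gaba;
    }

    // 4. threshold crossings
    spikers.clear();
    for (int j = 0; j < n; ++j)
      if (t_now >= refrac_until[j] && v[j] > v_th[j]) spikers.push_back(j);

    // 5. spike effects: reset, threshold bump, propagation, plasticity.
    //    last_spike is updated only after the whole step so that pairs of
    //    spikes within one step have dt == 0 and contribute nothing
    //    (the simultaneous branch of the STDP kernel).
    for (size_t k = 0; k < spikers.size(); ++k) {
      const int i = spikers[k];
      v[i] = v_rest;
      v_th[i] += eta_spike;
      refrac_until[i] = t_now + (i < nE ? refrac_E : refrac_I);
      if (record) {
        sp_step.push_back(s);
        sp_neuron.push_back(i);
      }
      // propagate through outgoing column i
      if (i < nE) {
        for (int post = 0; post < n; ++post) g_ampa[post] += W(post, i);
      } else {
        for (int post = 0; post < n; ++post) g_gaba[post] += W(post, i);
      }
      if (plastic && i < nE) {
        // potentiation of incoming E->E synapses (pre fired before post i)
        bool changed = false;
        for (int pre = 0; pre < nE; ++pre) {
          if (adjEE(i, pre) && last_spike[pre] > NEVER) {
            const double dtp = t_now - last_spike[pre]; // > 0
            W(i, pre) += A_plus * std::exp(-dtp / tau_plus);
            changed = true;
          }
        }
        if (changed && normalize) normalize_row(W, adjEE, i, nE, w_total);
        // depression of outgoing E->E synapses (post fired before pre i)
        for (int post = 0; post < nE; ++post) {
          if (adjEE(post, i) && last_spike[post] > NEVER) {
            const double dtd = last_spike[post] - t_now; // < 0
            W(post, i) -= A_minus * std::exp(dtd / tau_minus);
            if (W(post, i) < 0.0) W(post, i) = 0.0;
            if (normalize) normalize_row(W, adjEE, post, nE, w_total);
          }
        }
      }
    }
    for (size_t k = 0; k < spikers.size(); ++k)
      last_spike[spikers[k]] = t_now;

    // 6. guard against numerical blow-up
    double chk = 0.0;
    for (int j = 0; j < n; ++j) chk += v[j];
    if (!std::isfinite(chk)) {
      for (int j = 0; j < n; ++j)
        if (!std::isfinite(v[j]))
          stop("non-finite membrane potential for neuron %d at t = %.1f ms",
               j + 1, t_now);
    }
  }

  List out_state = List::create(
      _["v"] = v, _["g_ampa"] = g_ampa, _["g_gaba"] = g_gaba,
      _["v_th"] = v_th, _["refrac_until"] = refrac_until, _["xi"] = xi,
      _["last_spike"] = last_spike, _["t"] = t0 + n_steps * dt);
  return List::create(_["state"] = out_state, _["W"] = W,
                      _["spike_step"] = wrap(sp_step),
                      _["spike_neuron"] = wrap(sp_neuron));
}
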