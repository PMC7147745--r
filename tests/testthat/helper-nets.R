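# Small deterministic networks for unit tests.

# A noise-free "network" of isolated neurons (no synapses) for closed-form
# membrane checks. n neurons, first nE excitatory.
isolated_net <- function(n_E = 1, n_I = 1, params = NULL, seed = 1) {
  if (is.null(params)) params <- neuron_params(sigma_noise = 0)
  net <- init_network(params, seed = seed, n_E = n_E, n_I = n_I,
                      n_groups = 1, group_size = 1, p_connect = 0)
  n <- n_E + n_I
  net$state$v <- rep(params$v_rest, n)
  net$state$v_th <- rep(0, n) # unreachably high: no spiking unless lowered
  net$state$xi <- rep(0, n)
  net
}

# Fully-connected excitatory toy for plasticity tests (no inhibition used).
toy_plastic_net <- function(n_E = 3, params = NULL, seed = 1) {
  if (is.null(params)) params <- neuron_params(sigma_noise = 0)
  net <- init_network(params, seed = seed, n_E = n_E, n_I = 1,
                      n_groups = 1, group_size = 1, p_connect = 0)
  idx <- seq_len(n_E)
  adj <- matrix(TRUE, n_E, n_E); diag(adj) <- FALSE
  net$topology$adj[idx, idx] <- adj
  net$topology$W[idx, idx][adj] <- 1.0
  # cut the inhibitory neuron out entirely
  net$topology$adj[n_E + 1, ] <- FALSE
  net$topology$adj[, n_E + 1] <- FALSE
  net$topology$W[n_E + 1, ] <- 0
  net$topology$W[, n_E + 1] <- 0
  net$state$v <- rep(params$v_rest, n_E + 1)
  net$state$v_th <- rep(-67, n_E + 1)
  net$state$xi <- rep(0, n_E + 1)
  net
}

# Force listed neurons to spike at listed times via huge feedforward kicks;
# returns the recorded spikes (the kick fires the neuron on the next step).
force_spikes <- function(net, times_ms, neurons, duration_ms, kick = 100,
                         plasticity = TRUE) {
  ev <- data.frame(time_ms = times_ms, neuron = neurons, w = kick)
  run_steps(net, duration_ms, events = ev, plasticity = plasticity)
}
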