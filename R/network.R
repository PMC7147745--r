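#' Initialize the recurrent network
#'
#' Builds the fixed random topology (E->E without self-connections, E->I and
#' I->E, each edge present independently with probability `p_connect`; no
#' I->I connections) and the initial dynamical state. Recurrent excitatory
#' synapses start at 0.5 nS; all other synapses at 1.0 nS. The excitatory
#' population is partitioned at random into `n_groups` non-overlapping
#' groups of `group_size` neurons; the first five (labelled A-E) are the
#' trained sequence elements and the sixth (F) serves as the "external"
#' untrained target for distractors.
#'
#' Membrane potentials start uniform in \[v_rest, v_rest + 15\] mV and
#' thresholds uniform in \[v_rest, v_rest + 5\] mV, i.e. just above rest:
#' the intrinsic-plasticity equilibrium is then approached from below,
#' which is fast (spikes raise the threshold by 0.066 mV each), so the
#' 50 s warm-up phase erases the initialization. Starting thresholds far
#' above the operating point would instead converge only at the slow
#' 0.2 mV/s decay rate. The same `seed` yields a bit-identical network.
#'
#' @param params a [neuron_params()] bundle.
#' @param seed integer RNG seed.
#' @param n_E,n_I population sizes (defaults 200 excitatory, 40 inhibitory).
#' @param n_groups,group_size group structure of the excitatory population.
#' @param p_connect connection probability per potential edge.
#' @param w_ee_init,w_other_init initial synaptic strengths (nS).
#' @return A list of class `"spiking_network"` with elements `topology`
#'   (sizes, group assignment, adjacency masks, weight matrix `W` indexed
#'   `[post, pre]`) and `state` (voltages, conductances, thresholds,
#'   refractory clocks, OU noise state, last spike times, time `t`).
#' @export
init_network <- function(params = neuron_params(), seed = 1L,
                         n_E = 200L, n_I = 40L,
                         n_groups = 10L, group_size = 20L,
                         p_connect = 0.2, w_ee_init = 0.5,
                         w_other_init = 1.0) {
  validate_params(params)
  if (n_groups * group_size > n_E)
    stop("n_groups * group_size exceeds n_E", call. = FALSE)
  set.seed(seed)
  n <- n_E + n_I
  idx_E <- seq_len(n_E)
  idx_I <- n_E + seq_len(n_I)

  # adjacency masks, [post, pre]
  adj <- matrix(FALSE, n, n)
  adj[idx_E, idx_E] <- matrix(stats::runif(n_E * n_E) < p_connect, n_E, n_E)
  diag(adj)[idx_E] <- FALSE                     # no E->E self-connections
  adj[idx_I, idx_E] <- matrix(stats::runif(n_I * n_E) < p_connect, n_I, n_E)
  adj[idx_E, idx_I] <- matrix(stats::runif(n_E * n_I) < p_connect, n_E, n_I)
  # I->I absent by construction

  W <- matrix(0, n, n)
  W[idx_E, idx_E][adj[idx_E, idx_E]] <- w_ee_init
  W[idx_I, idx_E][adj[idx_I, idx_E]] <- w_other_init
  W[idx_E, idx_I][adj[idx_E, idx_I]] <- w_other_init

  group_assignment <- rep(NA_integer_, n_E)
  perm <- sample.int(n_E)
  for (g in seq_len(n_groups))
    group_assignment[perm[(g - 1L) * group_size + seq_len(group_size)]] <- g

  topology <- list(n_E = as.integer(n_E), n_I = as.integer(n_I),
                   n_groups = as.integer(n_groups),
                   group_size = as.integer(group_size),
                   group_assignment = group_assignment,
                   adj = adj, W = W, p_connect = p_connect)

  state <- list(
    v = stats::runif(n, params$v_rest, params$v_rest + 15),
    g_ampa = numeric(n),
    g_gaba = numeric(n),
    v_th = stats::runif(n, params$v_rest, params$v_rest + 5),
    refrac_until = rep(-Inf, n),
    xi = stats::rnorm(n),
    last_spike = rep(-1e18, n),
    t = 0
  )

  net <- list(topology = topology, state = state, params = params)
  class(net) <- "spiking_network"
  net
}

#' Neuron indices of a group
#'
#' @param topology the `topology` element of a network, or a network.
#' @param group group label: an integer 1..n_groups or a letter `"A"`..
#'   (`"A"`-`"E"` are the trained elements, `"F"` the external group).
#' @return integer vector of excitatory neuron indices (1-based).
#' @export
group_neurons <- function(topology, group) {
  if (inherits(topology, "spiking_network")) topology <- topology$topology
  if (is.character(group)) group <- match(toupper(group), LETTERS)
  if (is.na(group) || group < 1 || group > topology$n_groups)
    stop("unknown group", call. = FALSE)
  which(topology$group_assignment == group)
}

#' Advance the network dynamics
#'
#' Integrates the coupled membrane, conductance and threshold equations for
#' `duration_ms` with forward-Euler voltage updates and exact exponential
#' updates for conductance decay and the OU noise process. External input
#' spikes arrive as instantaneous AMPA conductance increments; spikes emitted
#' by the network are propagated through the weight matrix in the same step.
#' With `plasticity = TRUE`, nearest-neighbour STDP and (if enabled)
#' incoming-weight normalization act on E->E synapses online.
#'
#' @param net a `"spiking_network"`.
#' @param duration_ms span to simulate (ms); must be a multiple of `dt`.
#' @param events external input events: a data frame / matrix with columns
#'   `time_ms` (relative to the current network time), `neuron` (1-based
#'   index), `w` (conductance increment, nS); or `NULL`.
#' @param plasticity logical; enable STDP + normalization.
#' @param record logical; record emitted spikes.
#' @param I_ext constant external current (pA), scalar or per-neuron vector.
#' @return list with the updated `net` and `spikes`, a data frame with
#'   columns `time_ms` (absolute) and `neuron`.
#' @export
run_steps <- function(net, duration_ms, events = NULL, plasticity = FALSE,
                      record = TRUE, I_ext = 0) {
  p <- net$params
  dt <- p$dt
  n_steps <- as.integer(round(duration_ms / dt))
  n <- net$topology$n_E + net$topology$n_I
  if (length(I_ext) == 1) I_ext <- rep(I_ext, n)

  if (is.null(events) || NROW(events) == 0) {
    ev_step <- integer(0); ev_neuron <- integer(0); ev_w <- numeric(0)
  } else {
    events <- as.data.frame(events)
    stp <- as.integer(floor(events$time_ms / dt + 1e-9))
    keep <- stp >= 0 & stp < n_steps
    o <- order(stp[keep])
    ev_step <- stp[keep][o]
    ev_neuron <- as.integer(events$neuron[keep][o]) - 1L
    ev_w <- as.numeric(events$w[keep][o])
  }

  res <- sim_core(net$state, net$topology$W, net$topology$adj,
                  core_par(p, net$topology$n_E), n_steps,
                  ev_step, ev_neuron, ev_w, plasticity, record, I_ext)
  t0 <- net$state$t
  net$state <- res$state
  net$topology$W <- res$W
  spikes <- data.frame(time_ms = t0 + (res$spike_step + 1) * dt,
                       neuron = res$spike_neuron + 1L)
  list(net = net, spikes = spikes)
}

#' Excitatory-to-excitatory weight matrix
#'
#' @param net a `"spiking_network"` or its topology.
#' @return the E->E block of the weight matrix, `[post, pre]`, in nS.
#' @export
weights_EE <- function(net) {
  topo <- if (inherits(net, "spiking_network")) net$topology else net
  topo$W[seq_len(topo$n_E), seq_len(topo$n_E), drop = FALSE]
}

#' @export
print.spiking_network <- function(x, ...) {
  cat("<spiking_network> ", x$topology$n_E, "E / ", x$topology$n_I,
      "I neurons, t = ", format(x$state$t), " ms\n", sep = "")
  invisible(x)
}
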