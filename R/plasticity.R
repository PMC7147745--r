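#' STDP kernel
#'
#' Weight change contributed by a single pre/post spike pair with timing
#' difference `delta_t = t_post - t_pre`. Positive differences (pre before
#' post) potentiate by `A_plus * exp(-delta_t / tau_plus)`; negative
#' differences depress by `A_minus * exp(delta_t / tau_minus)` (returned
#' with negative sign); simultaneous spikes contribute nothing.
#'
#' @param delta_t signed timing difference `t_post - t_pre` (ms); vectorized.
#' @param params a [neuron_params()] bundle (only the STDP fields are used).
#' @return weight change in nS, same length as `delta_t`.
#' @export
#' @examples
#' stdp_kernel(20)   # 0.05 * exp(-1)
#' stdp_kernel(0)    # 0
stdp_kernel <- function(delta_t, params = neuron_params()) {
  ifelse(delta_t > 0, params$A_plus * exp(-delta_t / params$tau_plus),
         ifelse(delta_t < 0, -params$A_minus * exp(delta_t / params$tau_minus),
                0))
}

#' Offline nearest-neighbour STDP over full spike lists
#'
#' Reference implementation of the plasticity rule used online by the
#' simulation core: given the complete spike history of every neuron, each
#' spike is paired with the partner's most recent preceding spike only.
#' For synapse i -> j, every spike of j pairs with the last spike of i
#' before it (potentiation) and every spike of i pairs with the last spike
#' of j before it (depression). Weights are clipped at zero from below after
#' each change; normalization is applied after each spike's changes when
#' `params$normalize` is `TRUE`.
#'
#' This is the brute-force oracle the online core is tested against on
#' small instances; it is O(total spikes * n^2) and not meant for full runs.
#'
#' @param W_EE square E->E weight matrix `[post, pre]` (nS).
#' @param adj_EE logical adjacency of the same shape.
#' @param spike_times list of numeric vectors, `spike_times[[j]]` the sorted
#'   spike times (ms) of neuron j.
#' @param params a [neuron_params()] bundle.
#' @return the updated weight matrix.
#' @export
apply_stdp_offline <- function(W_EE, adj_EE, spike_times,
                               params = neuron_params()) {
  n <- nrow(W_EE)
  all_sp <- data.frame(
    time = unlist(spike_times, use.names = FALSE),
    neuron = rep(seq_along(spike_times), lengths(spike_times)))
  all_sp <- all_sp[order(all_sp$time), , drop = FALSE]
  last <- rep(-Inf, n)
  i_ev <- 1L
  while (i_ev <= nrow(all_sp)) {
    t_now <- all_sp$time[i_ev]
    batch <- all_sp$neuron[all_sp$time == t_now]
    for (s in batch) {
      changed <- FALSE
      for (pre in seq_len(n)) {
        if (adj_EE[s, pre] && is.finite(last[pre]) && last[pre] < t_now) {
          W_EE[s, pre] <- W_EE[s, pre] + stdp_kernel(t_now - last[pre], params)
          changed <- TRUE
        }
      }
      if (changed && params$normalize)
        W_EE <- normalize_incoming(W_EE, s, params, adj_EE)
      for (post in seq_len(n)) {
        if (adj_EE[post, s] && is.finite(last[post]) && last[post] < t_now) {
          W_EE[post, s] <- max(
            0, W_EE[post, s] + stdp_kernel(last[post] - t_now, params))
          if (params$normalize)
            W_EE <- normalize_incoming(W_EE, post, params, adj_EE)
        }
      }
    }
    last[batch] <- t_now
    i_ev <- i_ev + length(batch)
  }
  W_EE
}

#' Synaptic normalization of a neuron's incoming weights
#'
#' Rescales the incoming E->E weight vector of one excitatory neuron so that
#' its sum equals the homeostatic target `w_total`, preserving relative
#' proportions (and therefore zeros). A neuron with zero incoming sum is
#' left unchanged with a warning.
#'
#' @param W_EE square E->E weight matrix `[post, pre]` (nS).
#' @param neuron_index 1-based index of the postsynaptic neuron.
#' @param params a [neuron_params()] bundle (uses `w_total`).
#' @param adj_EE optional logical adjacency restricting which entries count;
#'   defaults to all off-diagonal entries.
#' @return the updated weight matrix.
#' @export
#' @examples
#' W <- rbind(c(0, 4, 4), c(0, 0, 0), c(0, 0, 0))
#' W[1, ] <- c(0, 4, 8)
#' normalize_incoming(W, 1)[1, ] # sums to 20
normalize_incoming <- function(W_EE, neuron_index, params = neuron_params(),
                               adj_EE = NULL) {
  if (is.null(adj_EE)) {
    mask <- rep(TRUE, ncol(W_EE))
    mask[neuron_index] <- FALSE
  } else {
    mask <- adj_EE[neuron_index, ]
  }
  s <- sum(W_EE[neuron_index, mask])
  if (s <= 0) {
    warning("incoming weight sum is zero for neuron ", neuron_index,
            "; normalization skipped")
    return(W_EE)
  }
  W_EE[neuron_index, mask] <- W_EE[neuron_index, mask] * params$w_total / s
  W_EE
}
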