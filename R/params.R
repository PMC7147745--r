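#' Neuron, plasticity and simulation parameters
#'
#' Returns the full parameter bundle for the network: membrane and synapse
#' constants of the conductance-based leaky integrate-and-fire model, the
#' intrinsic-plasticity (adaptive threshold) constants, the STDP and synaptic
#' normalization constants, and the integration settings. Defaults reproduce
#' the published shared simulation parameters exactly.
#'
#' Units: conductances nS, voltages mV, capacitance pF, times ms (except
#' `eta_decay_ip`, quoted in mV/s as published), currents pA.
#'
#' @param g_leak leak conductance (nS).
#' @param v_rest resting potential (mV).
#' @param c_membrane membrane capacitance (pF).
#' @param tau_membrane membrane time constant used by the noise term (ms).
#' @param tau_ampa,tau_gaba synaptic conductance decay time constants (ms).
#' @param e_ampa,e_gaba synaptic reversal potentials (mV).
#' @param eta_decay_ip adaptive-threshold decay rate (mV/s).
#' @param eta_spike_ip adaptive-threshold increment per spike (mV).
#' @param sigma_noise Ornstein-Uhlenbeck membrane noise amplitude (mV).
#' @param ou_tau correlation time of the OU noise process (ms); defaults to
#'   `tau_membrane`.
#' @param refrac_E,refrac_I absolute refractory periods of excitatory and
#'   inhibitory neurons (ms).
#' @param th_floor lower bound on the adaptive threshold (mV); a numerical
#'   guard placed below the operating range so the homeostatic equilibrium
#'   is never clipped.
#' @param ip_inhibitory logical; do inhibitory neurons share the adaptive
#'   threshold mechanism?
#' @param A_plus,A_minus STDP potentiation/depression amplitudes (nS).
#' @param tau_plus,tau_minus STDP decay time constants (ms).
#' @param w_total target total incoming excitatory weight per excitatory
#'   neuron for synaptic normalization (nS).
#' @param normalize logical; apply synaptic normalization after each
#'   STDP-induced change?
#' @param dt integration time step (ms).
#'
#' @return A named list of class `"neuron_params"`.
#' @export
#' @examples
#' p <- neuron_params()
#' p$g_leak # 30 nS
neuron_params <- function(g_leak = 30, v_rest = -70, c_membrane = 300,
                          tau_membrane = 20, tau_ampa = 2, tau_gaba = 5,
                          e_ampa = 0, e_gaba = -85,
                          eta_decay_ip = 0.2, eta_spike_ip = 0.066,
                          sigma_noise = 1, ou_tau = tau_membrane,
                          refrac_E = 10, refrac_I = 2,
                          th_floor = -80, ip_inhibitory = TRUE,
                          A_plus = 0.05, A_minus = 0.05,
                          tau_plus = 20, tau_minus = 20,
                          w_total = 20, normalize = TRUE,
                          dt = 0.1) {
  p <- list(g_leak = g_leak, v_rest = v_rest, c_membrane = c_membrane,
            tau_membrane = tau_membrane, tau_ampa = tau_ampa,
            tau_gaba = tau_gaba, e_ampa = e_ampa, e_gaba = e_gaba,
            eta_decay_ip = eta_decay_ip, eta_spike_ip = eta_spike_ip,
            sigma_noise = sigma_noise, ou_tau = ou_tau,
            refrac_E = refrac_E, refrac_I = refrac_I,
            th_floor = th_floor, ip_inhibitory = ip_inhibitory,
            A_plus = A_plus, A_minus = A_minus,
            tau_plus = tau_plus, tau_minus = tau_minus,
            w_total = w_total, normalize = normalize, dt = dt)
  class(p) <- "neuron_params"
  validate_params(p)
  p
}

#' Validate a parameter bundle
#'
#' Checks physical and numerical sanity of a [neuron_params()] bundle and
#' stops with an error naming the offending field.
#'
#' @param p a `"neuron_params"` list.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  chk_num <- function(field) {
    x <- p[[field]]
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop("parameter '", field, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  fields <- setdiff(names(p), c("ip_inhibitory", "normalize"))
  for (f in fields) chk_num(f)
  for (f in c("ip_inhibitory", "normalize"))
    if (!is.logical(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]))
      stop("parameter '", f, "' must be TRUE or FALSE", call. = FALSE)
  pos <- c("g_leak", "c_membrane", "tau_membrane", "tau_ampa", "tau_gaba",
           "refrac_E", "refrac_I", "tau_plus", "tau_minus", "dt")
  for (f in pos)
    if (p[[f]] <= 0)
      stop("parameter '", f, "' must be strictly positive", call. = FALSE)
  nonneg <- c("eta_decay_ip", "eta_spike_ip", "sigma_noise", "ou_tau",
              "A_plus", "A_minus", "w_total")
  for (f in nonneg)
    if (p[[f]] < 0)
      stop("parameter '", f, "' must be non-negative", call. = FALSE)
  if (!(p$e_gaba < p$v_rest && p$v_rest < p$e_ampa))
    stop("parameter 'v_rest' must satisfy e_gaba < v_rest < e_ampa",
         call. = FALSE)
  invisible(p)
}

# internal: params in the flat form the C++ core expects
core_par <- function(p, n_E) {
  c(p, list(n_E = as.integer(n_E)))
}
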