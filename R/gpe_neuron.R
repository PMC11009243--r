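#' Conductance-based leaky integrate-and-fire GPe neuron parameters
#'
#' The `IF_cond_exp` point-neuron: membrane capacitance `C`, leak towards
#' the passive potential `V_p` with time constant `tau_p` (leak conductance
#' `g_L = C / tau_p`), exponentially decaying excitatory and inhibitory
#' synaptic conductances with reversal potentials `E_exc` / `E_inh`, a
#' constant bias current `I_e`, and threshold/reset spiking with an
#' absolute refractory period.
#'
#' The voltage parameters follow conventional LIF values; the bias current
#' and noise amplitude are what get tuned (see [tune_gpe_bias()]) so the
#' population reproduces the pallidal rates observed off (~40.5 Hz) and
#' during (~100 Hz) subthalamic high-frequency stimulation.
#'
#' @param C membrane capacitance (pF).
#' @param tau_p passive membrane time constant (ms).
#' @param V_p passive (resting) potential (mV).
#' @param V_th spike threshold (mV).
#' @param V_r reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param E_exc,E_inh synaptic reversal potentials (mV).
#' @param I_e constant bias current (pA).
#' @return An object of class `gpe_params`.
#' @export
gpe_params <- function(C = 200, tau_p = 10, V_p = -65, V_th = -50,
                       V_r = -70, t_ref = 2, E_exc = 0, E_inh = -85,
                       I_e = 0) {
  stopifnot(V_r < V_th, tau_p > 0, E_inh < V_th, V_th < E_exc, C > 0,
            t_ref >= 0)
  structure(list(C = C, g_L = C / tau_p, tau_p = tau_p, V_p = V_p,
                 V_th = V_th, V_r = V_r, t_ref = t_ref, E_exc = E_exc,
                 E_inh = E_inh, I_e = I_e),
            class = "gpe_params")
}

#' One forward-Euler step of the LIF membrane equation
#'
#' Reference scalar implementation (the network simulator integrates the
#' same equation in compiled code). The membrane integrates
#' `C dV/dt = -g_L (V - V_p) - g_exc (V - E_exc) - g_inh (V - E_inh) + I_e
#' + i_noise`; crossing `V_th` emits a spike, resets to `V_r` and starts
#' the refractory clock.
#'
#' @param state list with `V` (mV) and `t_since_spike` (ms; `Inf` when not
#'   refractory).
#' @param params a [gpe_params()].
#' @param dt time step (ms); must not exceed 0.1 ms (the integration is
#'   explicit).
#' @param g_exc,g_inh synaptic conductances (nS), >= 0.
#' @param i_noise additional current (pA).
#' @return List `(state, spiked)`.
#' @export
lif_step <- function(state, params, dt, g_exc = 0, g_inh = 0, i_noise = 0) {
  stopifnot(dt > 0, dt <= 0.1 + 1e-12, g_exc >= 0, g_inh >= 0)
  V <- state$V
  tss <- state$t_since_spike + dt
  spiked <- FALSE
  if (tss < params$t_ref) {
    V <- params$V_r
  } else {
    dV <- (-params$g_L * (V - params$V_p) -
             g_exc * (V - params$E_exc) -
             g_inh * (V - params$E_inh) +
             params$I_e + i_noise) / params$C
    V <- V + dt * dV
    if (!is.finite(V)) {
      stop(sprintf("membrane voltage diverged (dt = %g ms); reduce dt", dt))
    }
    if (V >= params$V_th) {
      V <- params$V_r
      tss <- 0
      spiked <- TRUE
    }
  }
  list(state = list(V = V, t_since_spike = tss), spiked = spiked)
}

#' Closed-form firing rate of a current-driven LIF neuron
#'
#' For constant suprathreshold input current `I` and no noise the
#' interspike interval is `t_ref + tau_p * log((V_inf - V_r)/(V_inf -
#' V_th))` with `V_inf = V_p + I / g_L`; used as the analytic oracle for
#' the integrator.
#'
#' @param params a [gpe_params()].
#' @param I constant input current (pA).
#' @return Firing rate (Hz); 0 if subthreshold.
#' @export
lif_rate_analytic <- function(params, I) {
  V_inf <- params$V_p + I / params$g_L
  if (V_inf <= params$V_th) return(0)
  isi <- params$t_ref +
    params$tau_p * log((V_inf - params$V_r) / (V_inf - params$V_th))
  1000 / isi
}
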