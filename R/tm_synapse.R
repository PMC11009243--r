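#' Tsodyks-Markram synapse parameters
#'
#' Phenomenological short-term plasticity model with a utilization variable
#' `u` (calcium-dependent release probability) and a resource variable `r`
#' (fraction of available neurotransmitter). On each presynaptic spike `u`
#' jumps by `U * (1 - u)`, a quantum `A * u * r` is released, and `r` is
#' depleted by the released fraction; between spikes `u` relaxes to 0 with
#' time constant `tau_facil` and `r` recovers to 1 with `tau_rec`.
#'
#' `tau_facil = 0` denotes a depression-only synapse (`u` is pinned at `U`
#' on every spike, the conventional limit of the model); `tau_rec = 0`
#' denotes instantaneous recovery, i.e. a static synapse.
#'
#' @param U utilization increment per spike, in (0, 1].
#' @param tau_rec recovery time constant of `r` (ms); 0 = static synapse.
#' @param tau_facil facilitation time constant of `u` (ms); 0 = depression
#'   only.
#' @param A synaptic efficacy: conductance released by a spike at full
#'   utilization and full resources (nS-equivalent arbitrary units).
#' @param polarity `"excitatory"` or `"inhibitory"`; sets the default
#'   postsynaptic decay constant `tau_s` (3 ms and 5 ms respectively).
#' @param tau_s postsynaptic conductance decay constant (ms); defaults by
#'   polarity.
#' @return An object of class `tm_params`.
#' @export
tm_params <- function(U, tau_rec, tau_facil = 0, A = 1,
                      polarity = c("excitatory", "inhibitory"),
                      tau_s = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(tau_s)) tau_s <- if (polarity == "excitatory") 3 else 5
  stopifnot(is.numeric(U), length(U) == 1L, U > 0, U <= 1,
            tau_rec >= 0, tau_facil >= 0, A > 0, tau_s > 0)
  structure(list(U = U, tau_rec = tau_rec, tau_facil = tau_facil,
                 A = A, polarity = polarity, tau_s = tau_s),
            class = "tm_params")
}

#' @export
print.tm_params <- function(x, ...) {
  cat(sprintf("TM synapse (%s): U=%.3f tau_rec=%.1f ms tau_facil=%.1f ms A=%.3g tau_s=%.1f ms\n",
              x$polarity, x$U, x$tau_rec, x$tau_facil, x$A, x$tau_s))
  invisible(x)
}

#' Initial TM synapse state
#'
#' @param u initial utilization (0 for a rested synapse).
#' @param r initial resource fraction (1 for a rested synapse).
#' @param i_syn initial synaptic drive.
#' @return An object of class `tm_state`.
#' @export
tm_state <- function(u = 0, r = 1, i_syn = 0) {
  stopifnot(u >= 0, u <= 1, r >= 0, r <= 1)
  structure(list(u = u, r = r, i_syn = i_syn), class = "tm_state")
}

#' Advance a TM synapse by one time step
#'
#' Exact exponential relaxation of `u`, `r` and the postsynaptic drive over
#' `dt`, followed (if `spike_arrived`) by the per-spike map: `u+ = u +
#' U*(1-u)`, release `A * u+ * r`, then `r <- r - u+ * r`. The release
#' magnitude is added to the exponentially decaying drive `i_syn`.
#'
#' @param state a [tm_state()].
#' @param params a [tm_params()].
#' @param dt time step (ms), > 0.
#' @param spike_arrived logical: does a presynaptic spike arrive at the end
#'   of this step?
#' @return Updated `tm_state`, with attribute `"release"` holding the
#'   release magnitude of this step (0 if no spike).
#' @export
tm_step <- function(state, params, dt, spike_arrived = FALSE) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number (ms)")
  }
  if (any(!is.finite(c(state$u, state$r, state$i_syn)))) {
    stop("TM synapse state contains non-finite values")
  }
  u <- if (params$tau_facil > 0) state$u * exp(-dt / params$tau_facil) else 0
  r <- if (params$tau_rec > 0) 1 - (1 - state$r) * exp(-dt / params$tau_rec) else 1
  i_syn <- state$i_syn * exp(-dt / params$tau_s)
  release <- 0
  if (isTRUE(spike_arrived)) {
    u_plus <- u + params$U * (1 - u)
    release <- params$A * u_plus * r
    r <- r - u_plus * r
    u <- u_plus
    i_syn <- i_syn + release
  }
  out <- tm_state(u = u, r = r, i_syn = i_syn)
  attr(out, "release") <- release
  out
}

#' Per-pulse release amplitudes of a TM synapse under a periodic train
#'
#' Iterates the exact per-spike recursion (no time discretization): between
#' pulses separated by `T = 1000/frequency` ms, `u` and `r` relax
#' exponentially; at each pulse the per-spike map is applied. This is the
#' event-driven reference used both by the simulator and by the calibration
#' routine.
#'
#' @param params a [tm_params()].
#' @param frequency pulse rate (Hz), > 0.
#' @param n_pulses number of pulses.
#' @return Numeric vector of `n_pulses` release amplitudes.
#' @export
tm_release_train <- function(params, frequency, n_pulses) {
  stopifnot(frequency > 0, n_pulses >= 1)
  period <- 1000 / frequency
  ef <- if (params$tau_facil > 0) exp(-period / params$tau_facil) else 0
  er <- if (params$tau_rec > 0) exp(-period / params$tau_rec) else 0
  u <- 0; r <- 1
  rel <- numeric(n_pulses)
  for (k in seq_len(n_pulses)) {
    if (k > 1L) {
      u <- u * ef
      r <- 1 - (1 - r) * er
    }
    u <- u + params$U * (1 - u)
    rel[k] <- params$A * u * r
    r <- r - u * r
  }
  rel
}

#' Steady-state release fidelity of a synapse under periodic drive
#'
#' Mean release amplitude over the final 10% of pulses divided by the
#' first-pulse release; the conventional summary of how much transmission
#' persists under sustained stimulation (1 = fully resilient).
#'
#' @param params a [tm_params()].
#' @param frequency drive rate (Hz).
#' @param n_pulses length of the drive train (>= 30).
#' @return Fidelity ratio (unitless).
#' @export
steady_state_fidelity <- function(params, frequency, n_pulses = 100) {
  stopifnot(n_pulses >= 30, frequency > 0)
  rel <- tm_release_train(params, frequency, n_pulses)
  if (rel[1] <= 0) stop("degenerate synapse: first-pulse release is zero")
  tail_n <- max(1L, floor(n_pulses / 10))
  mean(rel[(n_pulses - tail_n + 1L):n_pulses]) / rel[1]
}

#' Calibrate a depressing TM synapse to a target steady-state fidelity
#'
#' The physiological literature reports projection fidelities (late-train
#' release as a fraction of the first pulse), not raw TM parameters. This
#' routine recovers parameters from a fidelity target by deterministic
#' bisection over `tau_rec` at fixed per-class `U` (depression-only,
#' `tau_facil = 0`): fidelity is monotone decreasing in `tau_rec`, so the
#' bracket is well defined.
#'
#' @param target_fidelity desired steady-state fidelity in (0, 1].
#' @param frequency calibration drive rate (Hz); the published fidelities
#'   refer to 100 Hz trains.
#' @param polarity passed to [tm_params()].
#' @param U fixed utilization constant of the class.
#' @param tau_facil fixed facilitation time constant of the class (ms);
#'   facilitation raises release at high rates, so a
#'   facilitating-depressing class can be near-resilient at low rates
#'   while the calibration pins its high-rate fidelity.
#' @param A synaptic efficacy of the returned parameters.
#' @param n_pulses train length used during calibration.
#' @param tol absolute fidelity tolerance of the bisection.
#' @return A [tm_params()] whose measured fidelity is within `tol` of the
#'   target.
#' @export
calibrate_synapse <- function(target_fidelity, frequency = 100,
                              polarity = c("excitatory", "inhibitory"),
                              U = 0.5, tau_facil = 0, A = 1,
                              n_pulses = 100, tol = 0.005) {
  polarity <- match.arg(polarity)
  stopifnot(target_fidelity > 0, target_fidelity <= 1)
  if (tau_facil == 0 && target_fidelity >= 1 - tol) {
    return(tm_params(U = U, tau_rec = 0, tau_facil = 0, A = A,
                     polarity = polarity))
  }
  f_of <- function(tau) {
    steady_state_fidelity(
      tm_params(U = U, tau_rec = tau, tau_facil = tau_facil, A = A,
                polarity = polarity),
      frequency, n_pulses)
  }
  lo <- 1e-3; hi <- 10 * 1000 / frequency
  while (f_of(hi) > target_fidelity && hi < 1e6) hi <- hi * 2
  if (f_of(hi) > target_fidelity || f_of(lo) < target_fidelity) {
    stop(sprintf(
      "calibration failure: target %.3f unreachable at %g Hz with U=%.2f (bracket fidelities [%.4f, %.4f] at tau_rec [%g, %g] ms)",
      target_fidelity, frequency, U, f_of(hi), f_of(lo), hi, lo))
  }
  mid <- (lo + hi) / 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    f_mid <- f_of(mid)
    if (abs(f_mid - target_fidelity) <= tol / 2) break
    if (f_mid > target_fidelity) lo <- mid else hi <- mid
  }
  tm_params(U = U, tau_rec = mid, tau_facil = tau_facil, A = A,
            polarity = polarity)
}
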