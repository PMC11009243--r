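#' Ornstein-Uhlenbeck noise process parameters
#'
#' Mean-reverting Gaussian process used as synaptic background noise on the
#' GPe population: `dx/dt = -(x - mu)/tau + alpha * sqrt(2/tau) * xi(t)`
#' with `xi` unit white noise. Under this scaling the stationary
#' distribution is `N(mu, alpha^2)`.
#'
#' @param mu stationary mean (current units, pA here).
#' @param alpha stationary standard deviation (same units).
#' @param tau time constant (ms); 5 ms in the mesocircuit defaults.
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(mu = 0, alpha = 0, tau = 5) {
  stopifnot(tau > 0, alpha >= 0)
  structure(list(mu = mu, alpha = alpha, tau = tau), class = "ou_params")
}

#' One exact-discretization step of an OU process
#'
#' Uses the exact transition density of the OU process over `dt` rather
#' than an Euler step, so the update is unbiased at any step size:
#' `x' = mu + (x - mu) e^(-dt/tau) + alpha sqrt(1 - e^(-2 dt/tau)) z`,
#' `z ~ N(0,1)`.
#'
#' @param x current value.
#' @param params an [ou_params()].
#' @param dt time step (ms), > 0.
#' @return Updated value (vectorized over `x`; one normal deviate per
#'   element, drawn from the R session RNG).
#' @export
ou_step <- function(x, params, dt) {
  stopifnot(dt > 0)
  decay <- exp(-dt / params$tau)
  x_det <- params$mu + (x - params$mu) * decay
  if (params$alpha == 0) return(x_det)
  x_det + params$alpha * sqrt(1 - decay^2) * stats::rnorm(length(x))
}

#' Simulate an OU path
#'
#' @param n number of steps.
#' @param params an [ou_params()].
#' @param dt time step (ms).
#' @param x0 initial value (default: the stationary mean).
#' @return Numeric vector of length `n + 1` including the initial value.
#' @export
ou_path <- function(n, params, dt, x0 = params$mu) {
  x <- numeric(n + 1)
  x[1] <- x0
  for (i in seq_len(n)) x[i + 1] <- ou_step(x[i], params, dt)
  x
}
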