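#' Mesocircuit network configuration
#'
#' Defines the abstract STN-GPe circuit: 100 Poisson STN units firing at
#' 39.9 Hz project onto 100 conductance-based integrate-and-fire GPe
#' neurons with per-neuron in-degree drawn uniformly from
#' `stn_to_gpe_indegree`; GPe neurons inhibit each other reciprocally with
#' in-degree drawn from `gpe_to_gpe_indegree` (`[20, 25]` = high, `[1, 5]`
#' = low reciprocal connectivity).
#'
#' @param n_stn,n_gpe population sizes.
#' @param stn_rate STN Poisson rate (Hz).
#' @param stn_to_gpe_indegree integer range `c(lo, hi)` of STN synapses per
#'   GPe neuron.
#' @param gpe_to_gpe_indegree integer range of reciprocal GPe synapses per
#'   GPe neuron.
#' @param weight_sd lognormal standard deviation (log scale) of
#'   per-synapse weight factors (mean 1). Synaptic weights in the pallidum
#'   are heterogeneous; this dispersion also grades the population's
#'   response to the competing pulse-locked excitation and inhibition
#'   instead of making all neurons cross threshold together.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_stn = 100, n_gpe = 100, stn_rate = 39.9,
                           stn_to_gpe_indegree = c(18, 22),
                           gpe_to_gpe_indegree = c(20, 25),
                           weight_sd = 0.6) {
  stopifnot(length(stn_to_gpe_indegree) == 2, length(gpe_to_gpe_indegree) == 2,
            all(stn_to_gpe_indegree >= 0), all(gpe_to_gpe_indegree >= 0),
            stn_rate >= 0, n_stn >= 1, n_gpe >= 2)
  if (stn_to_gpe_indegree[2] > n_stn) {
    stop("STN->GPe in-degree range exceeds the STN population size")
  }
  if (gpe_to_gpe_indegree[2] > n_gpe - 1) {
    stop("GPe->GPe in-degree range exceeds the available presynaptic pool")
  }
  stopifnot(weight_sd >= 0)
  structure(list(n_stn = n_stn, n_gpe = n_gpe, stn_rate = stn_rate,
                 stn_to_gpe_indegree = as.integer(stn_to_gpe_indegree),
                 gpe_to_gpe_indegree = as.integer(gpe_to_gpe_indegree),
                 weight_sd = weight_sd),
            class = "network_config")
}

#' Build the mesocircuit adjacency
#'
#' Samples, for each GPe neuron, an STN in-degree uniform in the configured
#' range and that many distinct presynaptic STN units, and likewise for the
#' reciprocal GPe->GPe projection (self-connections excluded). Sampling
#' uses the session RNG, so a fixed seed reproduces the adjacency exactly.
#'
#' @param config a [network_config()].
#' @param seed optional integer; when given, the RNG is seeded before
#'   sampling.
#' @return An object of class `mesocircuit_network`: the config plus
#'   edge lists `stn_gpe` and `gpe_gpe` (data frames with `pre`, `post`,
#'   1-based indices).
#' @export
build_network <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_edges <- function(n_post, pool, deg_range, exclude_self = FALSE) {
    pre <- integer(0); post <- integer(0)
    degs <- sample(deg_range[1]:deg_range[2], n_post, replace = TRUE)
    for (j in seq_len(n_post)) {
      cand <- if (exclude_self) setdiff(seq_len(pool), j) else seq_len(pool)
      src <- sample(cand, degs[j], replace = FALSE)
      pre <- c(pre, src)
      post <- c(post, rep.int(j, degs[j]))
    }
    w <- if (config$weight_sd > 0) {
      stats::rlnorm(length(pre), -config$weight_sd^2 / 2, config$weight_sd)
    } else rep(1, length(pre))
    data.frame(pre = pre, post = post, weight = w)
  }
  stn_gpe <- sample_edges(config$n_gpe, config$n_stn,
                          config$stn_to_gpe_indegree)
  gpe_gpe <- sample_edges(config$n_gpe, config$n_gpe,
                          config$gpe_to_gpe_indegree, exclude_self = TRUE)
  structure(list(config = config, stn_gpe = stn_gpe, gpe_gpe = gpe_gpe),
            class = "mesocircuit_network")
}

#' @export
print.mesocircuit_network <- function(x, ...) {
  cat(sprintf("STN-GPe mesocircuit: %d STN (Poisson %.1f Hz) -> %d GPe; %d STN->GPe and %d GPe->GPe synapses\n",
              x$config$n_stn, x$config$stn_rate, x$config$n_gpe,
              nrow(x$stn_gpe), nrow(x$gpe_gpe)))
  invisible(x)
}

#' DBS stimulation protocol
#'
#' A periodic pulse train plus the model of what each pulse activates:
#' (1a) a bank of 500 afferent synapses onto STN, 45% excitatory
#' (cortico-STN, rapidly depressing to ~10% fidelity) and 55% inhibitory
#' (GPe-STN, resilient at ~65%); (1b) the STN-GPe efferent synapses
#' (resilient, ~80% fidelity by default, or strictly static / strongly
#' depressing per `efferent_mode`) and, via antidromic invasion of GPe-STN
#' axon collaterals, the GPe-GPe synapses (~65%); (2) feedback GPe-STN
#' inhibition driven by the evoked GPe spiking itself. Pulse width is
#' metadata: pulses act as point events in the model.
#'
#' @param frequency pulse rate (Hz), 10-100 in the study conditions.
#' @param duration train duration (s).
#' @param pulse_width_ms pulse width metadata (ms); 0.3 ms biphasic.
#' @param n_afferent total afferent synapses activated per pulse.
#' @param frac_excitatory excitatory fraction of the afferent bank.
#' @param fidelity_targets named list of steady-state fidelity targets at
#'   100 Hz for each projection class.
#' @param efferent_mode `"resilient"` (calibrated to the efferent fidelity
#'   target), `"static"` (no depression) or `"depressing"` (calibrated to
#'   `depressing_fidelity`).
#' @param depressing_fidelity fidelity used when `efferent_mode =
#'   "depressing"`.
#' @param gpe_gpe_collaterals_enabled do pulses invade GPe-GPe collaterals?
#' @param hyperdirect_enabled are the excitatory cortico-STN afferents
#'   activated?
#' @return An object of class `dbs_protocol`.
#' @export
dbs_protocol <- function(frequency = 100, duration = 5,
                         pulse_width_ms = 0.3, n_afferent = 500,
                         frac_excitatory = 0.45,
                         fidelity_targets = list(cortico_stn = 0.10,
                                                 gpe_stn = 0.65,
                                                 gpe_gpe = 0.65,
                                                 stn_efferent = 0.80),
                         efferent_mode = c("resilient", "static",
                                           "depressing"),
                         depressing_fidelity = 0.20,
                         gpe_gpe_collaterals_enabled = TRUE,
                         hyperdirect_enabled = TRUE) {
  efferent_mode <- match.arg(efferent_mode)
  stopifnot(frequency > 0, duration >= 0, frac_excitatory >= 0,
            frac_excitatory <= 1, n_afferent >= 0)
  structure(list(frequency = frequency, duration = duration,
                 pulse_width_ms = pulse_width_ms, n_afferent = n_afferent,
                 frac_excitatory = frac_excitatory,
                 fidelity_targets = fidelity_targets,
                 efferent_mode = efferent_mode,
                 depressing_fidelity = depressing_fidelity,
                 gpe_gpe_collaterals_enabled = gpe_gpe_collaterals_enabled,
                 hyperdirect_enabled = hyperdirect_enabled),
            class = "dbs_protocol")
}

#' Pulse onset times of a protocol
#'
#' @param protocol a [dbs_protocol()].
#' @param t_start time of the first pulse (s).
#' @return Strictly increasing pulse times (s), spaced `1/frequency`.
#' @export
pulse_times <- function(protocol, t_start = 0) {
  n <- floor(protocol$duration * protocol$frequency)
  if (n <= 0) return(numeric(0))
  t_start + (seq_len(n) - 1) / protocol$frequency
}
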