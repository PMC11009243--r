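#' ERNA waveform template parameters
#'
#' Each stimulation pulse evokes a stereotyped high-frequency waveform
#' built from three Gaussian lobes: a first positive peak (P1, the direct
#' inhibitory afferent volley), a negative trough, and a second positive
#' peak (P2, the resonant feedback component). The trough and P2 are two
#' phases of the same resonant oscillation, so the trough depth scales
#' with the P2 amplitude (`trough_frac`). Along a 100 Hz train the
#' per-pulse amplitudes approach their late-train values exponentially in
#' the pulse index, so that the mean over pulses 40-45 relative to the
#' first pulse equals the configured dynamics targets; at stimulation
#' frequencies of 50 Hz and below the short-term dynamics that produce
#' these changes do not engage, and both targets are forced to 1.
#'
#' Latencies default to 3.2 ms (P1) and 6.3 ms (P2), placing both peaks
#' inside the 4-9 ms analysis window (P1 just ahead of it, as in the
#' recorded morphology) and the trough inside 5-7 ms; lobe width 0.5 ms
#' gives the ~300 Hz oscillatory appearance of ERNA.
#'
#' @param p1_latency,p2_latency peak latencies (ms post-pulse).
#' @param p1_amp0,p2_amp0 first-pulse amplitudes (uV).
#' @param p1_ratio_target,p2_ratio_target pulse-40-45 over first-pulse
#'   amplitude ratios at 100 Hz.
#' @param dynamics_tau time constant of the amplitude evolution (pulses).
#' @param lobe_width Gaussian lobe width (ms).
#' @param trough_frac trough depth as a fraction of the P2 amplitude.
#' @return An object of class `erna_template`.
#' @export
erna_template_params <- function(p1_latency = 3.2, p2_latency = 6.3,
                                 p1_amp0 = 150, p2_amp0 = 100,
                                 p1_ratio_target = 0.765,
                                 p2_ratio_target = 1.395,
                                 dynamics_tau = 8, lobe_width = 0.5,
                                 trough_frac = 0.3) {
  stopifnot(p1_ratio_target > 0, p2_ratio_target > 0, dynamics_tau > 0,
            lobe_width > 0, p1_latency < p2_latency)
  structure(list(p1_latency = p1_latency, p2_latency = p2_latency,
                 p1_amp0 = p1_amp0, p2_amp0 = p2_amp0,
                 p1_ratio_target = p1_ratio_target,
                 p2_ratio_target = p2_ratio_target,
                 dynamics_tau = dynamics_tau, lobe_width = lobe_width,
                 trough_frac = trough_frac),
            class = "erna_template")
}

# Per-pulse amplitude factor: exponential approach from 1 to `target`.
pulse_amp_factor <- function(pulse_index, target, tau) {
  target + (1 - target) * exp(-(pulse_index - 1) / tau)
}

#' Evaluate the ERNA waveform template
#'
#' @param t_since_pulse time since the pulse (ms); vectorized.
#' @param pulse_index 1-based pulse number within the train.
#' @param params an [erna_template_params()].
#' @param frequency stimulation frequency (Hz); at <= 50 Hz the dynamics
#'   targets are forced to 1 (frequency specificity of ERNA).
#' @return Waveform amplitude (uV).
#' @export
erna_waveform <- function(t_since_pulse, pulse_index, params, frequency = 100) {
  r1 <- params$p1_ratio_target
  r2 <- params$p2_ratio_target
  if (frequency <= 50) { r1 <- 1; r2 <- 1 }
  a1 <- params$p1_amp0 * pulse_amp_factor(pulse_index, r1, params$dynamics_tau)
  a2 <- params$p2_amp0 * pulse_amp_factor(pulse_index, r2, params$dynamics_tau)
  w <- params$lobe_width
  lobe <- function(lat) exp(-0.5 * ((t_since_pulse - lat) / w)^2)
  a1 * lobe(params$p1_latency) +
    a2 * lobe(params$p2_latency) -
    params$trough_frac * a2 * lobe((params$p1_latency + params$p2_latency) / 2)
}

#' Spiking model parameters for the synthetic recordings
#'
#' Single-unit spiking is an inhomogeneous Poisson process whose rate is
#' multiplicatively suppressed by the instantaneous (rectified) ERNA
#' amplitude — emulating inhibition time-locked to the waveform peaks and
#' proportional to their size: `rate(t) = baseline * exp(-gain *
#' max(erna(t), 0) / amp_ref)`. The exponential link guarantees a
#' non-negative rate; `amp_ref` puts the gain on the scale of the default
#' first-pulse P1 amplitude, so at the default gain the 100 uA condition
#' roughly halves interstimulus firing in the 4-9 ms window.
#'
#' @param baseline_rate pre-stimulation firing rate (Hz).
#' @param coupling_gain suppression strength (unitless, >= 0).
#' @param refractory_ms absolute refractory period enforced by deletion.
#' @param amp_ref amplitude scale of the gain (uV).
#' @return An object of class `spiking_params`.
#' @export
spiking_params <- function(baseline_rate = 35, coupling_gain = 6,
                           refractory_ms = 1, amp_ref = 150) {
  stopifnot(baseline_rate >= 0, coupling_gain >= 0, amp_ref > 0)
  structure(list(baseline_rate = baseline_rate,
                 coupling_gain = coupling_gain,
                 refractory_ms = refractory_ms, amp_ref = amp_ref),
            class = "spiking_params")
}

#' Generate spike times locked to an ERNA trace by thinning
#'
#' Inhomogeneous Poisson sampling (Lewis thinning against the baseline
#' rate, which is the exact supremum of the suppressed rate), followed by
#' refractory deletion.
#'
#' @param erna numeric ERNA trace (uV), sampled at `fs`.
#' @param fs sampling rate of `erna` (Hz).
#' @param params a [spiking_params()].
#' @return Sorted spike times (s).
#' @export
generate_spikes <- function(erna, fs, params) {
  dur <- length(erna) / fs
  if (params$baseline_rate <= 0) return(numeric(0))
  n <- stats::rpois(1, params$baseline_rate * dur)
  cand <- sort(stats::runif(n, 0, dur))
  if (length(cand) == 0) return(numeric(0))
  amp <- erna[pmin(length(erna), floor(cand * fs) + 1L)]
  keep_p <- exp(-params$coupling_gain * pmax(amp, 0) / params$amp_ref)
  spk <- cand[stats::runif(length(cand)) < keep_p]
  if (params$refractory_ms > 0 && length(spk) > 1) {
    ref_s <- params$refractory_ms / 1000
    keep <- rep(TRUE, length(spk))
    last <- spk[1]
    for (i in 2:length(spk)) {
      if (spk[i] - last < ref_s) keep[i] <- FALSE else last <- spk[i]
    }
    spk <- spk[keep]
  }
  spk
}

#' Generate one synthetic microelectrode recording
#'
#' Voltage = ERNA template train + band-limited Gaussian background noise
#' with the falling (~1/f^2) spectral profile of local field potentials
#' (10-250 Hz) + a brief biphasic artifact transient at each
#' pulse (1 ms, confined to the blanking window so it exercises the
#' blanking logic without contaminating the peaks). Includes a
#' pre-stimulation baseline for normalization. Spiking is generated by
#' [generate_spikes()] against the same ERNA train. Deterministic under
#' `seed`.
#'
#' Intensity scales the ERNA amplitude linearly (`intensity / 100` of the
#' template amplitudes); because spike suppression follows the realized
#' amplitude, higher intensities yield larger normalized ERNA and lower
#' interstimulus firing.
#'
#' @param seed integer RNG seed, or `NULL` to use the session RNG state.
#' @param frequency stimulation frequency (Hz).
#' @param duration_s stimulation train duration (s).
#' @param pre_s pre-stimulation baseline (s), >= 2 by default.
#' @param post_s run-out after the train (s).
#' @param intensity stimulation intensity (uA), one of the study's 30, 50,
#'   100 by convention.
#' @param fs sampling rate (Hz).
#' @param template an [erna_template_params()].
#' @param spiking a [spiking_params()].
#' @param noise_rms background-noise RMS in the 10-250 Hz band (uV).
#' @param site_scale multiplicative site-level amplitude factor.
#' @param artifact_amp stimulus-artifact amplitude (uV).
#' @param metadata extra metadata merged into the recording.
#' @return An [erna_recording()].
#' @export
generate_recording <- function(seed = NULL, frequency = 100,
                               duration_s = 10, pre_s = 2, post_s = 0.5,
                               intensity = 100, fs = 10000,
                               template = erna_template_params(),
                               spiking = spiking_params(),
                               noise_rms = 12, site_scale = 1,
                               artifact_amp = 400, metadata = list()) {
  if (!is.null(seed)) set.seed(seed)
  n_pulses <- floor(duration_s * frequency)
  pt <- pre_s + (seq_len(n_pulses) - 1) / frequency
  total_s <- pre_s + duration_s + post_s
  n <- round(total_s * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  amp_scale <- site_scale * intensity / 100

  erna <- numeric(n)
  isi_n <- round(fs / frequency)
  kernel_ms <- (seq_len(isi_n) - 1) / fs * 1000
  for (k in seq_len(n_pulses)) {
    i0 <- round(pt[k] * fs) + 1L
    idx <- i0:min(n, i0 + isi_n - 1L)
    erna[idx] <- erna[idx] +
      amp_scale * erna_waveform(kernel_ms[seq_along(idx)], k, template,
                                frequency)
  }

  # LFP-like background: integrated white noise (1/f^2 power profile)
  # confined to the 10-250 Hz band, scaled to the requested in-band RMS
  noise <- bandpass_lfp(cumsum(stats::rnorm(n)), fs)
  noise <- noise * noise_rms / sqrt(mean(noise^2))

  artifact <- numeric(n)
  art_half <- max(1L, round(0.0005 * fs))  # 0.5 ms per phase
  for (k in seq_len(n_pulses)) {
    i0 <- round(pt[k] * fs) + 1L
    up <- i0:min(n, i0 + art_half - 1L)
    dn <- (i0 + art_half):min(n, i0 + 2L * art_half - 1L)
    artifact[up] <- artifact[up] + artifact_amp
    artifact[dn] <- artifact[dn] - artifact_amp
  }

  spikes <- generate_spikes(erna, fs, spiking)
  md <- utils::modifyList(list(intensity = intensity, frequency = frequency,
                               site = NA), metadata)
  erna_recording(fs = fs, voltage = erna + noise + artifact,
                 pulse_times = pt, spike_times = spikes, metadata = md)
}

#' Synthetic cohort configuration
#'
#' Two study designs are emulated: `"spiking"` — 20 recording sites,
#' each stimulated at 30, 50 and 100 uA at 100 Hz (the
#' waveform-vs-spiking design); `"dynamics"` — 12 recording sites at
#' 100 uA, each stimulated at 10, 20, 30, 50 and 100 Hz (the
#' temporal-dynamics and frequency-specificity design). Site-to-site
#' amplitude variability is lognormal.
#'
#' @param style `"spiking"` or `"dynamics"`.
#' @param n_sites number of recording sites (defaults by style).
#' @param intensities stimulation intensities (uA).
#' @param frequencies stimulation frequencies (Hz).
#' @param duration_s train duration per recording (s).
#' @param site_sd_log lognormal sd of the site amplitude factor.
#' @param seed master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(style = c("spiking", "dynamics"), n_sites = NULL,
                          intensities = NULL, frequencies = NULL,
                          duration_s = 10, site_sd_log = 0.2, seed = 0) {
  style <- match.arg(style)
  if (style == "spiking") {
    if (is.null(n_sites)) n_sites <- 20
    if (is.null(intensities)) intensities <- c(30, 50, 100)
    if (is.null(frequencies)) frequencies <- 100
  } else {
    if (is.null(n_sites)) n_sites <- 12
    if (is.null(intensities)) intensities <- 100
    if (is.null(frequencies)) frequencies <- c(10, 20, 30, 50, 100)
  }
  structure(list(style = style, n_sites = n_sites,
                 intensities = intensities, frequencies = frequencies,
                 duration_s = duration_s, site_sd_log = site_sd_log,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic recording cohort
#'
#' One recording per site x intensity x frequency combination, with
#' lognormal site amplitude factors and per-recording seeds derived
#' deterministically from the master seed.
#'
#' @param config a [cohort_config()].
#' @param ... overrides passed to [generate_recording()] (e.g. a custom
#'   template).
#' @return List with `recordings` (list of [erna_recording()]) and
#'   `manifest` (data frame: site, intensity, frequency, site_scale,
#'   seed).
#' @export
generate_cohort <- function(config = cohort_config(), ...) {
  set.seed(config$seed)
  site_scale <- exp(stats::rnorm(config$n_sites, 0, config$site_sd_log))
  grid <- expand.grid(site = seq_len(config$n_sites),
                      intensity = config$intensities,
                      frequency = config$frequencies)
  grid <- grid[order(grid$site, grid$frequency, grid$intensity), ]
  grid$site_scale <- site_scale[grid$site]
  grid$seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  recordings <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    generate_recording(seed = g$seed, frequency = g$frequency,
                       duration_s = config$duration_s,
                       intensity = g$intensity, site_scale = g$site_scale,
                       metadata = list(site = g$site), ...)
  })
  rownames(grid) <- NULL
  list(recordings = recordings, manifest = grid)
}

#' Per-recording dynamics ratios of a cohort
#'
#' Runs the full analysis pipeline (normalization, segmentation, per-pulse
#' P1/P2 extraction, pulse-40-45 ratios) on every recording.
#'
#' @param cohort result of [generate_cohort()] or a plain list of
#'   recordings.
#' @param late_pulses passed to [peak_dynamics()].
#' @return Data frame: site, intensity, frequency, p1_ratio, p2_ratio.
#' @export
cohort_dynamics <- function(cohort, late_pulses = 40:45) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  rows <- lapply(recs, function(rec) {
    dyn <- peak_dynamics(peak_series(rec), late_pulses = late_pulses)
    data.frame(site = rec$metadata$site,
               intensity = rec$metadata$intensity,
               frequency = rec$metadata$frequency,
               p1_ratio = dyn$p1_ratio, p2_ratio = dyn$p2_ratio)
  })
  do.call(rbind, rows)
}
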