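#' Pre-stimulation RMS normalization constant
#'
#' Band-passes the pre-stimulation part of the trace (zero-phase 4th-order
#' Butterworth, 10-250 Hz by default — the conventional LFP band) and
#' returns its root-mean-square amplitude. All ERNA amplitudes in the
#' pipeline are expressed in units of this constant, which makes every
#' downstream statistic invariant to the recording gain.
#'
#' @param recording an [erna_recording()].
#' @param band band-pass corner frequencies (Hz).
#' @param margin_s guard interval excluded immediately before the first
#'   pulse (s).
#' @return The normalization constant (same units as the trace), > 0.
#' @export
prestim_rms <- function(recording, band = c(10, 250), margin_s = 0.01) {
  pre_s <- prestim_duration(recording) - margin_s
  min_s <- 10 / band[1]  # ten cycles of the low corner
  if (pre_s < min_s) {
    stop(sprintf("pre-stimulation window (%.2f s) too short for %g-%g Hz normalization (need >= %.1f s)",
                 pre_s, band[1], band[2], min_s))
  }
  n_pre <- floor(pre_s * recording$fs)
  x <- recording$voltage[seq_len(n_pre)]
  xf <- bandpass_lfp(x, recording$fs, band)
  # drop zero-phase filter edge transients from the RMS estimate
  trim <- min(round(0.2 * recording$fs), floor(n_pre / 5))
  xf <- xf[(trim + 1):(n_pre - trim)]
  rms <- sqrt(mean(xf^2))
  if (rms < .Machine$double.eps^0.25 * max(1, stats::sd(x), abs(mean(x)))) {
    stop("degenerate normalization: pre-stimulation LFP power in the 10-250 Hz band is ~0")
  }
  rms
}

# Zero-phase 4th-order Butterworth band-pass (2nd-order design applied
# forward and backward).
bandpass_lfp <- function(x, fs, band = c(10, 250)) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Segment a recording into interstimulus sweeps on a common grid
#'
#' One segment per pulse, spanning `blanking_ms` (stimulus-artifact
#' blanking) to the interstimulus interval after each pulse. Only pulses
#' with a complete following interval are kept. Each segment carries its
#' immediate pre-stimulus baseline (mean of the `baseline_ms` window
#' ending at the pulse), the reference for P1 amplitudes.
#'
#' @param recording an [erna_recording()].
#' @param blanking_ms post-pulse blanking (ms).
#' @param baseline_ms width of the immediate pre-stimulus baseline window
#'   (ms).
#' @return List with `time_ms` (grid, ms post-pulse), `segments` (matrix,
#'   pulses x samples), `baseline` (per-pulse), `isi_ms`.
#' @export
segment_interstim <- function(recording, blanking_ms = 1.5,
                              baseline_ms = 0.5) {
  pt <- recording$pulse_times
  if (length(pt) < 2) stop("need at least two pulses to segment")
  isi <- diff(pt)
  isi_ms <- stats::median(isi) * 1000
  if (any(abs(isi * 1000 - isi_ms) > 0.02 * isi_ms)) {
    stop("malformed pulse train: interstimulus intervals vary by more than 2%")
  }
  if (blanking_ms >= isi_ms) {
    stop("blanking window is not shorter than the interstimulus interval")
  }
  fs <- recording$fs
  i0 <- ceiling(blanking_ms * fs / 1000)
  i1 <- as.integer(round(isi_ms * fs / 1000)) - 1L
  idx_rel <- i0:i1
  nb <- max(1L, round(baseline_ms * fs / 1000))
  pulse_idx <- round(pt * fs) + 1L
  keep <- pulse_idx + i1 <= length(recording$voltage) &
    pulse_idx - nb >= 1L
  pulse_idx <- pulse_idx[keep]
  segments <- t(vapply(pulse_idx,
                       function(i) recording$voltage[i + idx_rel],
                       numeric(length(idx_rel))))
  baseline <- vapply(pulse_idx,
                     function(i) mean(recording$voltage[(i - nb):(i - 1L)]),
                     numeric(1))
  list(time_ms = idx_rel / fs * 1000, segments = segments,
       baseline = baseline, isi_ms = isi_ms, fs = fs,
       pulse_kept = which(keep))
}

#' Detect the P1 and P2 peaks of one interstimulus sweep
#'
#' After light smoothing (moving average, `smooth_ms` wide, for extremum
#' robustness), P1 and P2 are the dominant local maxima inside
#' `p1_window` and `p2_window` (the windows encode which ERNA peak is
#' which); P1 is measured against the immediate pre-stimulus baseline and
#' P2 against the intervening trough (the minimum between the two peak
#' latencies). Amplitudes are
#' divided by `norm`. A window with no interior local maximum yields `NA`
#' (peak not found), never zero.
#'
#' @param values sweep samples.
#' @param time_ms sample times (ms post-pulse).
#' @param baseline immediate pre-stimulus baseline (same units as
#'   `values`).
#' @param norm normalization constant (pre-stimulation LFP RMS).
#' @param p1_window,p2_window search windows (ms post-pulse).
#' @param smooth_ms moving-average width (ms); 0 disables smoothing.
#' @param fs sampling rate (Hz), needed when `smooth_ms > 0`.
#' @return List with `p1`, `p2` (normalized amplitudes or `NA`),
#'   `p1_latency_ms`, `p2_latency_ms`, `trough_ms`.
#' @export
detect_p1_p2 <- function(values, time_ms, baseline = 0, norm = 1,
                         p1_window = c(2, 5), p2_window = c(5, 9),
                         smooth_ms = 0.3, fs = NULL) {
  v <- values
  if (smooth_ms > 0) {
    if (is.null(fs)) fs <- 1000 / stats::median(diff(time_ms))
    k <- max(1L, round(smooth_ms * fs / 1000))
    if (k > 1L) v <- stats::filter(values, rep(1 / k, k), sides = 2)
    v <- as.numeric(v)
  }
  local_max <- function(win) {
    idx <- which(time_ms >= win[1] & time_ms <= win[2])
    idx <- idx[idx > 1 & idx < length(v)]
    idx[!is.na(v[idx]) & v[idx] >= v[idx - 1] & v[idx] > v[idx + 1]]
  }
  out <- list(p1 = NA_real_, p2 = NA_real_, p1_latency_ms = NA_real_,
              p2_latency_ms = NA_real_, trough_ms = NA_real_)
  m1 <- local_max(p1_window)
  if (length(m1)) {
    i1 <- m1[which.max(v[m1])]  # dominant peak inside the P1 window
    out$p1 <- (v[i1] - baseline) / norm
    out$p1_latency_ms <- time_ms[i1]
  }
  m2 <- local_max(p2_window)
  if (length(m1) && length(m2)) m2 <- m2[m2 > m1[1]]
  if (length(m2)) {
    i2 <- m2[which.max(v[m2])]
    lo <- if (length(m1)) m1[1] else which(time_ms >= p1_window[1])[1]
    between <- lo:i2
    it <- between[which.min(v[between])]
    out$p2 <- (v[i2] - v[it]) / norm
    out$p2_latency_ms <- time_ms[i2]
    out$trough_ms <- time_ms[it]
  }
  out
}

#' Per-pulse P1/P2 amplitude series of a recording
#'
#' Segments the recording, normalizes by the pre-stimulation LFP RMS and
#' applies [detect_p1_p2()] to every sweep.
#'
#' @param recording an [erna_recording()].
#' @param blanking_ms stimulus-artifact blanking (ms).
#' @param p1_window,p2_window,smooth_ms passed to [detect_p1_p2()].
#' @param norm normalization constant; computed by [prestim_rms()] when
#'   `NULL`.
#' @return Data frame of class `peak_series`: `pulse_index`, `p1`, `p2`,
#'   `p1_latency_ms`, `p2_latency_ms`; the normalization constant is the
#'   `"norm"` attribute.
#' @export
peak_series <- function(recording, blanking_ms = 1.5,
                        p1_window = c(2, 5), p2_window = c(5, 9),
                        smooth_ms = 0.3, norm = NULL) {
  if (is.null(norm)) norm <- prestim_rms(recording)
  seg <- segment_interstim(recording, blanking_ms = blanking_ms)
  rows <- lapply(seq_len(nrow(seg$segments)), function(i) {
    d <- detect_p1_p2(seg$segments[i, ], seg$time_ms,
                      baseline = seg$baseline[i], norm = norm,
                      p1_window = p1_window, p2_window = p2_window,
                      smooth_ms = smooth_ms, fs = seg$fs)
    data.frame(pulse_index = seg$pulse_kept[i], p1 = d$p1, p2 = d$p2,
               p1_latency_ms = d$p1_latency_ms,
               p2_latency_ms = d$p2_latency_ms)
  })
  out <- do.call(rbind, rows)
  attr(out, "norm") <- norm
  class(out) <- c("peak_series", class(out))
  out
}

#' Temporal-dynamics summary of a peak series
#'
#' The standard summary of how the waveform evolves along the train: the
#' mean amplitude over pulses 40-45 divided by the first-pulse amplitude,
#' separately for P1 and P2.
#'
#' @param series a [peak_series()] data frame.
#' @param late_pulses pulse indices averaged for the late-train amplitude.
#' @return List with `p1_ratio` and `p2_ratio`.
#' @export
peak_dynamics <- function(series, late_pulses = 40:45) {
  need <- c(1L, late_pulses)
  if (!all(need %in% series$pulse_index)) {
    stop("peak series must cover pulse 1 and the late-train pulses")
  }
  first <- series[series$pulse_index == 1L, ]
  late <- series[series$pulse_index %in% late_pulses, ]
  ratio <- function(peak) {
    f <- first[[peak]]
    if (is.na(f) || f == 0) {
      stop(sprintf("undefined dynamics: first-pulse %s missing or zero",
                   toupper(peak)))
    }
    mean(late[[peak]], na.rm = TRUE) / f
  }
  list(p1_ratio = ratio("p1"), p2_ratio = ratio("p2"))
}

#' Normalized interstimulus waveform average
#'
#' @param recording an [erna_recording()].
#' @param blanking_ms stimulus-artifact blanking (ms).
#' @param norm normalization constant; [prestim_rms()] when `NULL`.
#' @return List of class `waveform_average`: `time_ms`, `mean_waveform`
#'   (units of pre-stimulation RMS), `n_segments`.
#' @export
waveform_average <- function(recording, blanking_ms = 1.5, norm = NULL) {
  if (is.null(norm)) norm <- prestim_rms(recording)
  seg <- segment_interstim(recording, blanking_ms = blanking_ms)
  structure(list(time_ms = seg$time_ms,
                 mean_waveform = colMeans(seg$segments) / norm,
                 n_segments = nrow(seg$segments), norm = norm),
            class = "waveform_average")
}

#' Interstimulus peristimulus time histogram
#'
#' Folds spike times over all interstimulus intervals and converts counts
#' to rates; the pre-stimulation firing rate is reported alongside as the
#' baseline.
#'
#' @param spike_times spike timestamps (s).
#' @param pulse_times pulse onsets (s), regular train.
#' @param bin_ms bin width (ms); must tile the interstimulus interval.
#' @param baseline_window `c(t0, t1)` window (s) for the baseline rate;
#'   defaults to everything before the first pulse.
#' @return List of class `psth`: `bin_edges_ms`, `rate_hz` per bin,
#'   `baseline_rate_hz`, `n_intervals`.
#' @export
build_psth <- function(spike_times, pulse_times, bin_ms = 0.5,
                       baseline_window = NULL) {
  stopifnot(length(pulse_times) >= 2)
  isi_ms <- stats::median(diff(pulse_times)) * 1000
  n_bins <- round(isi_ms / bin_ms)
  if (abs(n_bins * bin_ms - isi_ms) > 1e-6 * isi_ms) {
    stop(sprintf("bin width %g ms does not tile the %g ms interstimulus interval",
                 bin_ms, isi_ms))
  }
  edges <- seq(0, isi_ms, by = bin_ms)
  n_int <- length(pulse_times)
  train_end <- pulse_times[length(pulse_times)] + isi_ms / 1000
  in_train <- spike_times >= pulse_times[1] & spike_times < train_end
  if (any(in_train)) {
    rel <- spike_times[in_train] -
      pulse_times[findInterval(spike_times[in_train], pulse_times)]
    counts <- graphics::hist(rel * 1000, breaks = edges, plot = FALSE)$counts
  } else {
    counts <- rep(0L, n_bins)
  }
  rate <- counts / n_int / (bin_ms / 1000)
  if (is.null(baseline_window)) baseline_window <- c(0, pulse_times[1])
  bl_dur <- diff(baseline_window)
  baseline <- if (bl_dur > 0) {
    sum(spike_times >= baseline_window[1] &
          spike_times < baseline_window[2]) / bl_dur
  } else NA_real_
  structure(list(bin_edges_ms = edges, rate_hz = rate,
                 baseline_rate_hz = baseline, n_intervals = n_int),
            class = "psth")
}

#' Mean PSTH rate inside a latency window
#'
#' @param psth a [build_psth()] result.
#' @param window `c(t0, t1)` (ms post-pulse).
#' @param stat `"mean"` or `"min"` (the local minimum, used for the
#'   trough-firing statistic).
#' @return Rate (Hz).
#' @export
psth_window_rate <- function(psth, window, stat = c("mean", "min")) {
  stat <- match.arg(stat)
  centers <- psth$bin_edges_ms[-length(psth$bin_edges_ms)] +
    diff(psth$bin_edges_ms) / 2
  sel <- centers >= window[1] & centers <= window[2]
  if (!any(sel)) stop("window contains no PSTH bins")
  if (stat == "mean") mean(psth$rate_hz[sel]) else min(psth$rate_hz[sel])
}
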