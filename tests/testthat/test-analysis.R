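test_that("pre-stimulation RMS recovers a sinusoid's a/sqrt(2)", {
  fs <- 10000
  t <- seq(0, 4, by = 1 / fs)
  a <- 20
  rec <- erna_recording(fs, a * sin(2 * pi * 100 * t),
                        pulse_times = 3.5)
  expect_equal(prestim_rms(rec), a / sqrt(2), tolerance = 0.02)
})

test_that("degenerate and too-short baselines are refused", {
  fs <- 10000
  rec_dc <- erna_recording(fs, rep(5, 3 * fs), pulse_times = 2.5)
  expect_error(prestim_rms(rec_dc), "degenerate")
  rec_short <- erna_recording(fs, rnorm(fs), pulse_times = 0.5)
  expect_error(prestim_rms(rec_short), "too short")
})

test_that("band-limited RMS of white noise matches a spectral oracle", {
  set.seed(21)
  fs <- 10000
  x <- rnorm(4 * fs, sd = 3)
  rec <- erna_recording(fs, x, pulse_times = 3.9)
  got <- prestim_rms(rec)
  # oracle: periodogram of the raw trace weighted by the zero-phase
  # Butterworth response (|H|^2 applied twice = |H|^4 in power)
  n <- floor((3.9 - 0.01) * fs)
  xs <- x[seq_len(n)]
  pw <- abs(fft(xs))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  bf <- signal::butter(2, c(10, 250) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fs)
  evalpoly <- function(coefs) {
    acc <- 0
    for (c0 in coefs) acc <- acc * z + c0
    acc
  }
  H <- evalpoly(rev(bf$b)) / evalpoly(rev(bf$a))
  expect_equal(got, sqrt(sum(pw * abs(H)^4)), tolerance = 0.05)
})

test_that("segmentation yields one full interstimulus sweep per usable pulse", {
  fs <- 10000
  rec <- erna_recording(fs, rnorm(10 * fs), pulse_times = (0:999) / 100)
  seg <- segment_interstim(rec, blanking_ms = 1.5)
  expect_equal(nrow(seg$segments), 999)     # first pulse lacks a baseline
  expect_equal(seg$isi_ms, 10)
  expect_equal(range(seg$time_ms), c(1.5, 9.9), tolerance = 1e-8)

  rec10 <- erna_recording(fs, rnorm(10 * fs), pulse_times = (0:99) / 10)
  expect_equal(nrow(segment_interstim(rec10)$segments), 99)
  seg2 <- segment_interstim(rec, blanking_ms = 2)
  expect_equal(min(seg2$time_ms), 2)

  expect_error(segment_interstim(rec, blanking_ms = 12), "blanking")
  bad <- erna_recording(fs, rnorm(fs), pulse_times = c(0.1, 0.2, 0.5))
  expect_error(segment_interstim(bad), "malformed")
})

test_that("a flat sweep yields peak-not-found, never zero", {
  t_ms <- seq(1.5, 9.9, by = 0.1)
  d <- detect_p1_p2(rep(0, length(t_ms)), t_ms, fs = 10000)
  expect_true(is.na(d$p1))
  expect_true(is.na(d$p2))
})

test_that("peaks of an analytic two-lobe sweep are recovered exactly", {
  t_ms <- seq(1.5, 9.9, by = 0.1)
  tmpl <- erna_template_params()
  v <- erna_waveform(t_ms, pulse_index = 1, tmpl)
  d <- detect_p1_p2(v, t_ms, baseline = 0, norm = 1, smooth_ms = 0)
  expect_equal(d$p1_latency_ms, tmpl$p1_latency, tolerance = 0.11)
  expect_equal(d$p2_latency_ms, tmpl$p2_latency, tolerance = 0.11)
  expect_equal(d$p1, tmpl$p1_amp0, tolerance = 0.005)
  # P2 is measured against the intervening trough (trough_frac of the P2
  # lobe); 2% slack covers the analytic overlap of the Gaussian lobes
  expect_equal(d$p2, tmpl$p2_amp0 * (1 + tmpl$trough_frac),
               tolerance = 0.02)
})

test_that("dynamics ratios reduce to direct arithmetic", {
  ps <- data.frame(pulse_index = 1:45, p1 = rep(4, 45), p2 = rep(2, 45))
  d <- peak_dynamics(ps)
  expect_equal(d$p1_ratio, 1)
  expect_equal(d$p2_ratio, 1)

  p1 <- seq(4, 2, length.out = 45)          # halves linearly by pulse 45
  ps2 <- data.frame(pulse_index = 1:45, p1 = p1, p2 = p1)
  expect_equal(peak_dynamics(ps2)$p1_ratio, mean(p1[40:45]) / p1[1])

  ps3 <- ps; ps3$p1[1] <- NA
  expect_error(peak_dynamics(ps3), "undefined dynamics")
  expect_error(peak_dynamics(ps[1:30, ]), "late-train")
})

test_that("PSTH of homogeneous Poisson spiking is flat at the true rate", {
  set.seed(33)
  pulses <- 2 + (0:999) / 100
  spikes <- sort(runif(round(40 * 14), 0, 14))
  ps <- build_psth(spikes, pulses, bin_ms = 0.5)
  expect_equal(length(ps$rate_hz), 20)
  expect_equal(mean(ps$rate_hz), 40, tolerance = 0.1)
  expect_equal(ps$baseline_rate_hz, 40, tolerance = 0.25)
  # all-zero case
  z <- build_psth(numeric(0), pulses)
  expect_true(all(z$rate_hz == 0))
  expect_error(build_psth(spikes, pulses, bin_ms = 0.7), "tile")
})

test_that("spikes thinned at 5-7 ms produce a PSTH trough there", {
  set.seed(34)
  pulses <- 2 + (0:999) / 100
  spikes <- sort(runif(40 * 14, 0, 14))
  rel <- (spikes - 2) %% 0.01
  drop <- spikes > 2 & rel > 0.005 & rel < 0.007 & runif(length(spikes)) < 0.9
  ps <- build_psth(spikes[!drop], pulses)
  expect_lt(psth_window_rate(ps, c(5, 7), "min"),
            0.5 * psth_window_rate(ps, c(0.5, 4.5), "mean"))
})

test_that("all normalized outputs are invariant to the recording gain", {
  rec <- make_recording(seed = 8, duration_s = 0.8)
  rec2 <- rec
  rec2$voltage <- rec$voltage * 37.5
  a <- peak_series(rec)
  b <- peak_series(rec2)
  expect_equal(a$p1, b$p1, tolerance = 1e-10)
  expect_equal(a$p2, b$p2, tolerance = 1e-10)
  wa <- waveform_average(rec); wb <- waveform_average(rec2)
  expect_equal(wa$mean_waveform, wb$mean_waveform, tolerance = 1e-10)
})

test_that("outputs are invariant to a common time shift", {
  rec <- make_recording(seed = 9, duration_s = 0.8)
  shift_n <- 3507                            # samples
  shift_s <- shift_n / rec$fs
  rec2 <- erna_recording(rec$fs,
                         c(rec$voltage[(shift_n + 1):length(rec$voltage)]),
                         pulse_times = rec$pulse_times - shift_s,
                         spike_times = rec$spike_times - shift_s,
                         metadata = rec$metadata)
  a <- peak_series(rec, norm = 1)
  b <- peak_series(rec2, norm = 1)
  expect_equal(a$p1, b$p1, tolerance = 1e-12)
  expect_equal(a$p2, b$p2, tolerance = 1e-12)
  pa <- build_psth(rec$spike_times, rec$pulse_times)
  pb <- build_psth(rec2$spike_times, rec2$pulse_times)
  expect_equal(pa$rate_hz, pb$rate_hz, tolerance = 1e-12)
})
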