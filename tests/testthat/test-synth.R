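test_that("noise-free generation round-trips through the analysis exactly", {
  rec <- generate_recording(seed = 1, duration_s = 1, noise_rms = 0,
                            artifact_amp = 0)
  ps <- peak_series(rec, norm = 1, smooth_ms = 0)
  tmpl <- erna_template_params()
  one_sample_ms <- 1000 / rec$fs
  expect_lt(max(abs(ps$p1_latency_ms - tmpl$p1_latency)), 1.5 * one_sample_ms)
  expect_lt(max(abs(ps$p2_latency_ms - tmpl$p2_latency)), 1.5 * one_sample_ms)
  a1 <- tmpl$p1_amp0 *
    (tmpl$p1_ratio_target + (1 - tmpl$p1_ratio_target) *
       exp(-(ps$pulse_index - 1) / tmpl$dynamics_tau))
  expect_equal(ps$p1, a1, tolerance = 0.02)
  d <- peak_dynamics(ps)
  expect_equal(d$p1_ratio, 0.766, tolerance = 0.01)
  expect_equal(d$p2_ratio, 1.393, tolerance = 0.01)
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_recording(seed = 123, duration_s = 0.5)
  b <- generate_recording(seed = 123, duration_s = 0.5)
  expect_identical(a$voltage, b$voltage)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("low-frequency trains embed no peak dynamics", {
  # mean over a few recordings: a single sweep-referenced ratio carries
  # a few percent of measurement noise
  for (f in c(20, 50)) {
    d <- rowMeans(sapply(5:8, function(sd) {
      rec <- generate_recording(seed = sd, frequency = f,
                                duration_s = 50 / f + 0.2)
      unlist(peak_dynamics(peak_series(rec)))
    }))
    expect_gt(d["p1_ratio"], 0.95)
    expect_lt(d["p1_ratio"], 1.05)
    expect_gt(d["p2_ratio"], 0.95)
    expect_lt(d["p2_ratio"], 1.05)
  }
})

test_that("intensity scales ERNA up and interstimulus firing down", {
  r100 <- generate_recording(seed = 6, duration_s = 4, intensity = 100)
  r30 <- generate_recording(seed = 6, duration_s = 4, intensity = 30)
  tab <- erna_firing_table(list(
    { r100$metadata$site <- 1; r100 },
    { r30$metadata$site <- 2; r30 }))
  amp100 <- tab$log_erna_amp_4_9ms[tab$intensity == 100]
  amp30 <- tab$log_erna_amp_4_9ms[tab$intensity == 30]
  expect_gt(amp100, amp30)
  expect_lt(tab$mean_firing_4_9ms[tab$intensity == 100],
            tab$mean_firing_4_9ms[tab$intensity == 30])
})

test_that("cohort designs have the study's dimensions", {
  spk <- cohort_config(style = "spiking")
  expect_equal(spk$n_sites * length(spk$intensities), 60)
  small <- generate_cohort(cohort_config(style = "spiking", n_sites = 3,
                                         duration_s = 2, seed = 2))
  expect_length(small$recordings, 9)
  expect_equal(nrow(small$manifest), 9)

  dyncfg <- cohort_config(style = "dynamics")
  expect_equal(dyncfg$n_sites, 12)
  expect_equal(dyncfg$frequencies, c(10, 20, 30, 50, 100))
})

test_that("ERNA-locked suppression deepens the PSTH trough with gain", {
  # window-mean rate at 5-7 ms: the bin-wise minimum saturates at zero
  # for strong gains, the window rate stays strictly ordered
  troughs <- sapply(c(1, 4, 10), function(g) {
    rec <- generate_recording(seed = 9, duration_s = 8,
                              spiking = spiking_params(coupling_gain = g))
    psth_window_rate(build_psth(rec$spike_times, rec$pulse_times),
                     c(5, 7), "mean")
  })
  expect_true(all(diff(troughs) < 0))
})

test_that("uncoupled spiking is homogeneous Poisson at the baseline rate", {
  set.seed(10)
  rec <- generate_recording(seed = 10, duration_s = 8,
                            spiking = spiking_params(baseline_rate = 35,
                                                     coupling_gain = 0,
                                                     refractory_ms = 0))
  n <- length(rec$spike_times)
  dur <- length(rec$voltage) / rec$fs
  expect_equal(n / dur, 35, tolerance = 0.1)
  isi <- diff(rec$spike_times)
  ks <- suppressWarnings(ks.test(isi, "pexp", rate = n / dur))
  expect_gt(ks$p.value, 0.01)

  none <- generate_spikes(rep(0, 1000), 10000,
                          spiking_params(baseline_rate = 0))
  expect_length(none, 0)
})
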