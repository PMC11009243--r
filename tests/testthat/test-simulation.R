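test_that("identical seeds give identical simulations", {
  net <- build_network(seed = 5)
  proto <- dbs_protocol(duration = 0.5)
  a <- run_simulation(net, proto, seed = 5, extract_peaks = FALSE)
  b <- run_simulation(net, proto, seed = 5, extract_peaks = FALSE)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$proxy, b$proxy)
})

test_that("the ERNA proxy is non-negative and relaxes after the train", {
  net <- build_network(seed = 2)
  r <- run_simulation(net, dbs_protocol(duration = 1), seed = 2,
                      pre_s = 1.2, post_s = 0.6, extract_peaks = FALSE)
  expect_true(all(r$proxy >= 0))
  fs <- r$fs
  base <- mean(r$proxy[seq(round(0.2 * fs), round(1.1 * fs))])
  train_end <- 1.2 + 1
  late <- mean(r$proxy[seq(round((train_end + 0.5) * fs),
                           round((train_end + 0.6) * fs))])
  peak <- max(r$proxy)
  expect_lt(abs(late - base), 0.05 * peak)
})

test_that("a pulse-free protocol leaves the network at its baseline rate", {
  net <- build_network(seed = 4)
  r <- run_simulation(net, dbs_protocol(duration = 0), seed = 4, pre_s = 3,
                      post_s = 0, extract_peaks = FALSE)
  expect_equal(r$gpe_rate_off, 40.5, tolerance = 0.15)
  expect_equal(r$stn_rate_empirical, 39.9, tolerance = 0.05)
})

test_that("a coarse integration step for the pulse grid is refused", {
  net <- build_network(seed = 1)
  p <- mesocircuit_params(dt = 2)
  expect_error(run_simulation(net, dbs_protocol(frequency = 100,
                                                duration = 1), p),
               "too coarse")
})

test_that("unknown scenario labels are rejected with the valid set", {
  expect_error(run_scenario("lfs_40", n_iterations = 1),
               "hfs_full")
})

test_that("disabling collaterals removes pulse-locked GPe-GPe releases", {
  # with collaterals off and reciprocal connectivity removed, the only
  # inhibition left is the OU-free baseline: the on-rate rises sharply
  net <- build_network(network_config(gpe_to_gpe_indegree = c(0, 0)),
                       seed = 9)
  on <- run_simulation(net, dbs_protocol(
    duration = 0.5, gpe_gpe_collaterals_enabled = FALSE), seed = 9,
    extract_peaks = FALSE)$gpe_rate_on
  full <- run_simulation(build_network(seed = 9),
                         dbs_protocol(duration = 0.5), seed = 9,
                         extract_peaks = FALSE)$gpe_rate_on
  expect_gt(on, full * 1.5)
})

test_that("the in-silico peak series covers every delivered pulse", {
  net <- build_network(seed = 6)
  r <- run_simulation(net, dbs_protocol(duration = 0.6), seed = 6)
  expect_s3_class(r$peak_series, "peak_series")
  expect_equal(nrow(r$peak_series), 60)
  expect_true(all(is.finite(r$peak_series$p2[40:45])))
})
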