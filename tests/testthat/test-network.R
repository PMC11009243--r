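test_that("in-degrees fall inside the configured ranges", {
  net <- build_network(network_config(), seed = 3)
  stn_deg <- table(factor(net$stn_gpe$post, levels = 1:100))
  expect_true(all(stn_deg >= 18 & stn_deg <= 22))
  gg_deg <- table(factor(net$gpe_gpe$post, levels = 1:100))
  expect_true(all(gg_deg >= 20 & gg_deg <= 25))
  expect_true(all(net$gpe_gpe$pre != net$gpe_gpe$post))

  low <- build_network(network_config(gpe_to_gpe_indegree = c(1, 5)), seed = 3)
  low_deg <- table(factor(low$gpe_gpe$post, levels = 1:100))
  expect_true(all(low_deg >= 1 & low_deg <= 5))
})

test_that("identical seeds reproduce the adjacency exactly", {
  a <- build_network(seed = 7)
  b <- build_network(seed = 7)
  expect_identical(a$stn_gpe, b$stn_gpe)
  expect_identical(a$gpe_gpe, b$gpe_gpe)
})

test_that("impossible in-degree ranges are rejected", {
  expect_error(network_config(stn_to_gpe_indegree = c(50, 150)),
               "in-degree")
  expect_error(network_config(gpe_to_gpe_indegree = c(10, 100)),
               "in-degree")
})

test_that("the DBS afferent bank has 500 synapses, 45% excitatory", {
  proto <- dbs_protocol()
  expect_equal(proto$n_afferent, 500)
  expect_equal(proto$frac_excitatory, 0.45)
  n_exc <- round(proto$n_afferent * proto$frac_excitatory)
  expect_equal(n_exc, 225)
  expect_equal(proto$n_afferent - n_exc, 275)
})

test_that("pulse trains are regular and scale with frequency", {
  pt <- pulse_times(dbs_protocol(frequency = 100, duration = 2), t_start = 1)
  expect_length(pt, 200)
  expect_true(all(abs(diff(pt) - 0.01) < 1e-12))
  expect_length(pulse_times(dbs_protocol(duration = 0)), 0)
})
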