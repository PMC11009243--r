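test_that("unknown experiment ids are refused with the valid set", {
  expect_error(run_experiment("nonesuch"), "waveform_spiking")
})

test_that("the dynamics experiment writes reproducible per-site tables", {
  d1 <- file.path(tempdir(), "expA")
  d2 <- file.path(tempdir(), "expB")
  rep1 <- run_experiment("peak_dynamics_cohort", seed = 0, out_dir = d1)
  rep2 <- run_experiment("peak_dynamics_cohort", seed = 0, out_dir = d2)
  f1 <- file.path(d1, "peak_dynamics_cohort", "dynamics.csv")
  f2 <- file.path(d2, "peak_dynamics_cohort", "dynamics.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  dyn <- rep1$tables$dynamics
  expect_equal(nrow(dyn), 12)
  expect_true(is.finite(rep1$tables$stats$rho_p1_vs_p2))
  expect_identical(rep1$provenance, rep2$provenance)
  rep3 <- run_experiment("peak_dynamics_cohort", seed = 1, out_dir = d1)
  expect_false(identical(rep1$provenance, rep3$provenance))
})

test_that("acceptance checking compares against the registry", {
  reg <- acceptance_registry()
  expect_equal(nrow(reg), 8)
  res <- check_acceptance(list(gpe_rate_off_hz = 40.9,
                               fidelity_cortico_stn_pct = 10.2))
  expect_true(res$pass[res$id == "gpe_rate_off_hz"])
  expect_true(res$pass[res$id == "fidelity_cortico_stn_pct"])
  expect_true(all(is.na(res$pass[!res$id %in%
    c("gpe_rate_off_hz", "fidelity_cortico_stn_pct")])))
  res_empty <- check_acceptance(list())
  expect_true(all(is.na(res_empty$pass)))
  bad <- acceptance_registry()
  bad$tolerance[1] <- 0
  expect_error(check_acceptance(list(gpe_rate_off_hz = 40), registry = bad),
               "misconfigured")
})
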