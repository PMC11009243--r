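test_that("a rested synapse with no spikes is a fixed point", {
  p <- tm_params(U = 0.5, tau_rec = 100, tau_facil = 20)
  s <- tm_step(tm_state(), p, dt = 5)
  expect_equal(s$u, 0)
  expect_equal(s$r, 1)
  expect_equal(s$i_syn, 0)
  expect_equal(attr(s, "release"), 0)
})

test_that("relaxation between spikes follows the stated time constants", {
  p <- tm_params(U = 0.3, tau_rec = 80, tau_facil = 40)
  s0 <- tm_state(u = 0.6, r = 0.4, i_syn = 2)
  s <- tm_step(s0, p, dt = 10)
  expect_equal(s$u, 0.6 * exp(-10 / 40))
  expect_equal(s$r, 1 - (1 - 0.4) * exp(-10 / 80))
  expect_equal(s$i_syn, 2 * exp(-10 / p$tau_s))
})

test_that("depression-only periodic steady state matches the closed-form fixed point", {
  # r* = (1 - e^(-T/tau_rec)) / (1 - (1-U) e^(-T/tau_rec)); release_n = A U r_n
  for (U in c(0.2, 0.5, 0.9)) for (frequency in c(20, 100)) {
    tau_rec <- 40
    p <- tm_params(U = U, tau_rec = tau_rec)
    x <- exp(-1000 / frequency / tau_rec)
    r_star <- (1 - x) / (1 - (1 - U) * x)
    rel <- tm_release_train(p, frequency, 200)
    expect_equal(rel[200] / rel[1], r_star, tolerance = 1e-10)
    expect_equal(steady_state_fidelity(p, frequency, 200), r_star,
                 tolerance = 1e-6)
  }
})

test_that("stepped simulation matches the exact per-pulse recursion to 1e-9", {
  set.seed(42)
  for (k in 1:20) {
    p <- tm_params(U = runif(1, 0.05, 0.95), tau_rec = runif(1, 5, 300),
                   tau_facil = sample(c(0, runif(1, 5, 100)), 1))
    frequency <- sample(c(10, 20, 50, 100), 1)
    period_ms <- 1000 / frequency
    n_sub <- 20                      # sub-steps per interstimulus interval
    dt <- period_ms / n_sub
    oracle <- tm_release_train(p, frequency, 30)
    s <- tm_state()
    got <- numeric(30)
    for (pulse in 1:30) {
      if (pulse > 1) for (j in seq_len(n_sub)) s <- tm_step(s, p, dt)
      s <- tm_step(s, p, dt = 1e-9, spike_arrived = TRUE)
      got[pulse] <- attr(s, "release")
    }
    expect_lt(max(abs(got - oracle) / oracle), 1e-9)
  }
})

test_that("static and fully recovering synapses have unit fidelity", {
  static <- tm_params(U = 0.5, tau_rec = 0)
  expect_equal(steady_state_fidelity(static, 100), 1.0)
  slow_drive <- tm_params(U = 0.5, tau_rec = 2)   # T = 100 ms >> tau_rec
  expect_equal(steady_state_fidelity(slow_drive, 10), 1.0, tolerance = 1e-6)
})

test_that("calibration hits the published projection fidelities at 100 Hz", {
  for (target in c(0.10, 0.65, 0.80)) {
    p <- calibrate_synapse(target, 100)
    expect_lt(abs(steady_state_fidelity(p, 100) - target), 0.01)
  }
  expect_equal(calibrate_synapse(1.0, 100)$tau_rec, 0)
})

test_that("calibration round-trips across random targets", {
  set.seed(7)
  for (target in runif(12, 0.05, 0.95)) {
    p <- calibrate_synapse(target, 100, U = 0.9)
    expect_lt(abs(steady_state_fidelity(p, 100) - target), 0.01)
  }
  # with a facilitating class too
  for (target in c(0.3, 0.65, 0.9)) {
    p <- calibrate_synapse(target, 100, U = 0.2, tau_facil = 25)
    expect_lt(abs(steady_state_fidelity(p, 100) - target), 0.01)
  }
})

test_that("degenerate inputs raise informative errors", {
  p <- tm_params(U = 0.5, tau_rec = 50)
  expect_error(tm_step(tm_state(), p, dt = 0), "dt")
  bad <- tm_state(); bad$u <- NaN
  expect_error(tm_step(bad, p, dt = 1), "non-finite")
  expect_error(tm_params(U = 0, tau_rec = 10))
  expect_error(calibrate_synapse(1.5, 100))
  expect_error(steady_state_fidelity(tm_params(U = 0.5, tau_rec = 10), 100,
                                     n_pulses = 10))
})
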