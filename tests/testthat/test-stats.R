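test_that("noise-free common-slope data is fit exactly", {
  d <- expand.grid(site = factor(1:6), x = c(0, 1, 2))
  d$y <- -13 * d$x + as.numeric(d$site)          # distinct intercepts
  # zero residual variance makes the optimizer grumble; the estimate is
  # still exact
  fit <- suppressWarnings(fit_mixed_slope(d, "x", "y", "site"))
  expect_equal(fit$slope, -13, tolerance = 1e-6)
})

test_that("with zero group variance the mixed slope equals OLS", {
  set.seed(15)
  d <- expand.grid(site = factor(1:8), x = 1:3)
  d$y <- 2.5 * d$x + rnorm(nrow(d))              # no site effect at all
  fit <- fit_mixed_slope(d, "x", "y", "site")
  ols <- unname(coef(lm(y ~ x, d))["x"])
  expect_equal(fit$slope, ols, tolerance = 1e-5)
})

test_that("the mixed model recovers a known slope with nominal coverage", {
  set.seed(16)
  beta <- -7
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    d <- expand.grid(site = factor(1:20), x = c(0, 0.5, 1))
    d$y <- beta * d$x + rnorm(20, sd = 2)[as.integer(d$site)] +
      rnorm(nrow(d), sd = 1)
    fit <- fit_mixed_slope(d, "x", "y", "site")
    ci <- fit$slope + c(-1, 1) * qt(0.975, fit$df) * fit$se
    if (beta >= ci[1] && beta <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("Spearman matches a brute-force rank oracle on all permutations", {
  for (n in 3:5) {
    x <- seq_len(n)
    perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                   drop = FALSE]
    for (i in seq_len(nrow(perms))) {
      y <- as.numeric(perms[i, ])
      expect_equal(spearman_rho(x, y), rank_rho(x, y), tolerance = 1e-12)
    }
  }
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
})

test_that("within-site consistency reproduces a hand-computed t test", {
  # three sites engineered to give rho = -1, -0.5, +0.5
  tab <- data.frame(
    site = rep(c("a", "b", "c"), each = 3),
    intensity = rep(c(30, 50, 100), 3),
    log_erna_amp_4_9ms = rep(1:3, 3),
    mean_firing_4_9ms = c(3, 2, 1, 2, 3, 1, 2, 1, 3),
    log_p2_amp = rep(1:3, 3),
    trough_firing_5_7ms = rep(1, 9),
    complete = TRUE)
  res <- within_site_consistency(tab)
  expect_equal(unname(sort(res$rho)), c(-1, -0.5, 0.5))
  rho <- c(-1, -0.5, 0.5)
  t_hand <- mean(rho) / (sd(rho) / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p_bonferroni, min(1, res$p_raw * 4))
})

test_that("identical rho values across sites are flagged degenerate", {
  tab <- data.frame(
    site = rep(c("a", "b", "c"), each = 3),
    intensity = rep(c(30, 50, 100), 3),
    log_erna_amp_4_9ms = rep(1:3, 3),
    mean_firing_4_9ms = rep(c(3, 2, 1), 3),
    log_p2_amp = rep(1:3, 3),
    trough_firing_5_7ms = rep(1, 9),
    complete = TRUE)
  res <- within_site_consistency(tab)
  expect_true(res$degenerate)
  expect_equal(res$p_raw, 0)
  expect_true(all(res$rho == -1))
})

test_that("the site-statistics table has one row per site and intensity", {
  cohort <- generate_cohort(cohort_config(style = "spiking", n_sites = 5,
                                          duration_s = 4, seed = 1))
  tab <- erna_firing_table(cohort$recordings)
  expect_equal(nrow(tab), 15)
  expect_true(all(table(tab$site) == 3))
  # larger ERNA comes with less interstimulus firing by construction
  expect_lt(spearman_rho(tab$log_erna_amp_4_9ms, tab$mean_firing_4_9ms), 0)
  res <- within_site_consistency(tab)
  expect_lt(res$mean_rho, 0)
})

test_that("zero-amplitude recordings are excluded, not log-transformed", {
  recs <- c(
    lapply(c(30, 50, 100), function(int) {
      generate_recording(seed = int, duration_s = 3, intensity = int,
                         metadata = list(site = 1))
    }),
    lapply(c(30, 50, 100), function(int) {
      generate_recording(seed = int + 7, duration_s = 3, intensity = int,
                         site_scale = 0, metadata = list(site = 2))
    }))
  # an amplitude floor of 0.1 RMS units marks the signal-free site as
  # undefined rather than taking the log of residual averaging noise
  tab <- erna_firing_table(recs, min_amp = 0.1)
  expect_true(all(is.na(tab$log_erna_amp_4_9ms[tab$site == 2])))
  expect_true(all(!tab$complete[tab$site == 2]))
  expect_true(all(tab$complete[tab$site == 1]))
})
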