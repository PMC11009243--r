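#' Windowed ERNA-amplitude and firing statistics per site and intensity
#'
#' For each recording: the log rectified normalized ERNA amplitude of the
#' interstimulus waveform average and the mean interstimulus firing rate,
#' both constrained to the 4-9 ms window that captures P1 and P2; the log
#' P2 amplitude of the average waveform; and the local minimum of firing
#' in the 5-7 ms window (the trough statistic). Amplitudes below
#' `min_amp` (in RMS units) are flagged undefined rather than
#' log-transformed.
#'
#' @param cohort list of [erna_recording()]s whose metadata carry `site`
#'   and `intensity`.
#' @param amp_window,trough_window latency windows (ms post-pulse).
#' @param blanking_ms stimulus-artifact blanking (ms).
#' @param min_amp rectified-amplitude floor (units of pre-stim RMS) below
#'   which the log is treated as undefined.
#' @return Data frame: `site`, `intensity`, `log_erna_amp_4_9ms`,
#'   `mean_firing_4_9ms`, `log_p2_amp`, `trough_firing_5_7ms`, and a
#'   `complete` flag (sites missing an intensity or with undefined
#'   amplitudes are excluded from within-site statistics).
#' @export
erna_firing_table <- function(cohort, amp_window = c(4, 9),
                              trough_window = c(5, 7),
                              blanking_ms = 1.5, min_amp = 1e-6) {
  rows <- lapply(cohort, function(rec) {
    wa <- waveform_average(rec, blanking_ms = blanking_ms)
    sel <- wa$time_ms >= amp_window[1] & wa$time_ms <= amp_window[2]
    amp <- mean(abs(wa$mean_waveform[sel]))
    d <- detect_p1_p2(wa$mean_waveform, wa$time_ms, baseline = 0, norm = 1)
    ps <- build_psth(rec$spike_times, rec$pulse_times)
    data.frame(
      site = rec$metadata$site,
      intensity = rec$metadata$intensity,
      log_erna_amp_4_9ms = if (amp > min_amp) log(amp) else NA_real_,
      mean_firing_4_9ms = psth_window_rate(ps, amp_window, "mean"),
      log_p2_amp = if (!is.na(d$p2) && abs(d$p2) > min_amp) log(abs(d$p2))
                   else NA_real_,
      trough_firing_5_7ms = psth_window_rate(ps, trough_window, "min"))
  })
  out <- do.call(rbind, rows)
  n_int <- length(unique(out$intensity))
  by_site <- split(out, out$site)
  complete_sites <- names(Filter(function(d) {
    nrow(d) == n_int && !anyNA(d$log_erna_amp_4_9ms) && !anyNA(d$log_p2_amp)
  }, by_site))
  out$complete <- as.character(out$site) %in% complete_sites
  rownames(out) <- NULL
  out
}

#' Mixed-effects slope of firing on log ERNA amplitude
#'
#' Fits a linear mixed-effects model `response ~ predictor + (1 |
#' grouping)` (random intercept per recording site) and reports the fixed
#' slope with its standard error, t statistic, Satterthwaite degrees of
#' freedom and p-value. A singular fit (zero estimated site variance, in
#' which case the slope equals the ordinary least-squares slope) is
#' reported through the `singular` flag, not silently.
#'
#' @param table a data frame.
#' @param predictor,response,grouping column names.
#' @return List: `slope`, `se`, `t`, `df`, `p`, `singular`, `fit`.
#' @export
fit_mixed_slope <- function(table, predictor, response, grouping = "site") {
  d <- table[stats::complete.cases(table[, c(predictor, response, grouping)]), ]
  if (length(unique(d[[grouping]])) < 2) {
    stop("need at least two grouping levels for a mixed model")
  }
  f <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)",
                                 response, predictor, grouping))
  fit <- lmerTest::lmer(f, data = d,
                        control = lme4::lmerControl(
                          check.conv.singular = lme4::.makeCC(
                            action = "ignore", tol = 1e-4)))
  co <- stats::coef(summary(fit))
  list(slope = co[predictor, "Estimate"],
       se = co[predictor, "Std. Error"],
       t = co[predictor, "t value"],
       df = co[predictor, "df"],
       p = co[predictor, "Pr(>|t|)"],
       singular = lme4::isSingular(fit),
       fit = fit)
}

#' Spearman rank correlation
#'
#' Thin wrapper over [stats::cor()] with average ranks for ties; returns
#' `NA` when either variable is constant (rho undefined).
#'
#' @param x,y numeric vectors.
#' @return Rho in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Within-site consistency of the ERNA-firing association
#'
#' Computes the Spearman rho between a predictor and a response across the
#' (few, typically 3) stimulation intensities recorded at each site, then
#' tests the site-level rho values against 0 with a one-sample two-tailed
#' t test. Sites whose rho is undefined (tied/constant triples) are
#' excluded and reported. The p-value is Bonferroni-corrected for the
#' module's four hypothesis tests by default.
#'
#' @param table output of [erna_firing_table()] (only `complete` rows are
#'   used).
#' @param predictor,response column names.
#' @param n_hypotheses Bonferroni correction factor.
#' @return List: `rho` (named per site), `mean_rho`, `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `excluded_sites`, `degenerate` (TRUE when the rho
#'   values have zero variance, in which case p is reported as 0).
#' @export
within_site_consistency <- function(table,
                                    predictor = "log_erna_amp_4_9ms",
                                    response = "mean_firing_4_9ms",
                                    n_hypotheses = 4) {
  d <- table[table$complete, ]
  by_site <- split(d, droplevels(factor(d$site)))
  rho <- vapply(by_site, function(s) {
    s <- s[order(s$intensity), ]
    spearman_rho(s[[predictor]], s[[response]])
  }, numeric(1))
  excluded <- names(rho)[is.na(rho)]
  rho <- rho[!is.na(rho)]
  if (length(rho) < 2) stop("fewer than two sites with defined rho")
  degenerate <- stats::sd(rho) == 0
  if (degenerate) {
    tt <- list(statistic = c(t = sign(mean(rho)) * Inf),
               parameter = c(df = length(rho) - 1), p.value = 0)
  } else {
    tt <- stats::t.test(rho, mu = 0)
  }
  p_raw <- tt$p.value
  list(rho = rho, mean_rho = mean(rho),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = p_raw, p_bonferroni = min(1, p_raw * n_hypotheses),
       excluded_sites = excluded, degenerate = degenerate)
}

#' Full waveform-spiking statistics battery for a cohort
#'
#' The four hypothesis tests linking the ERNA waveform to interstimulus
#' spiking: two across-site mixed-effects slopes (overall 4-9 ms amplitude
#' vs firing; P2 amplitude vs 5-7 ms trough firing) and the two matching
#' within-site Spearman consistency tests, all Bonferroni-corrected
#' together.
#'
#' @param table output of [erna_firing_table()].
#' @return Nested list with `across` and `within` components.
#' @export
waveform_spiking_stats <- function(table) {
  across_amp <- fit_mixed_slope(table, "log_erna_amp_4_9ms",
                                "mean_firing_4_9ms")
  across_p2 <- fit_mixed_slope(table, "log_p2_amp", "trough_firing_5_7ms")
  within_amp <- within_site_consistency(table, "log_erna_amp_4_9ms",
                                        "mean_firing_4_9ms")
  within_p2 <- within_site_consistency(table, "log_p2_amp",
                                       "trough_firing_5_7ms")
  adj <- function(p) min(1, p * 4)
  list(across = list(amplitude_vs_firing = c(across_amp[c("slope", "se", "t",
                                                          "df")],
                                             p_bonferroni = adj(across_amp$p)),
                     p2_vs_trough = c(across_p2[c("slope", "se", "t", "df")],
                                      p_bonferroni = adj(across_p2$p))),
       within = list(amplitude_vs_firing = within_amp,
                     p2_vs_trough = within_p2))
}
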