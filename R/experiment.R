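#' Valid experiment identifiers
#' @return Character vector of experiment ids.
#' @export
experiment_ids <- function() {
  c("waveform_spiking", "peak_dynamics_cohort", "circuit_scenarios",
    "frequency_sweep")
}

# Small stable polynomial hash of a string; used only for provenance
# stamps (not cryptographic).
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 68719476731
  format(h, scientific = FALSE)
}

#' Run one end-to-end experiment and write its tables
#'
#' Orchestrates the reproduction pipelines:
#' \describe{
#'   \item{`waveform_spiking`}{synthetic 20-site x 3-intensity cohort ->
#'     windowed site statistics, mixed-effects slopes and within-site
#'     Spearman consistency (`site_stats.csv`, `stats_summary.json`).}
#'   \item{`peak_dynamics_cohort`}{synthetic 12-site 100 Hz cohort ->
#'     per-site
#'     P1/P2 dynamics ratios and their Spearman association
#'     (`dynamics.csv`, `stats_summary.json`).}
#'   \item{`circuit_scenarios`}{in-silico scenario battery (full circuit,
#'     20 Hz LFS, depressing efferent, no GPe-GPe) averaged over
#'     iterations (`scenario_dynamics.csv`, per-condition mean peak
#'     series).}
#'   \item{`frequency_sweep`}{in-silico frequency sweep 10-100 Hz
#'     (`lfs_dynamics.csv`).}
#' }
#'
#' @param experiment_id one of [experiment_ids()].
#' @param seed master seed.
#' @param n_iterations model iterations for simulator experiments.
#' @param out_dir output directory (created, namespaced per experiment).
#' @return A `run_report` list: experiment id, seed, provenance hash,
#'   summary tables and output file paths.
#' @export
run_experiment <- function(experiment_id, seed = 0, n_iterations = 10,
                           out_dir = "results") {
  if (!experiment_id %in% experiment_ids()) {
    stop(sprintf("unknown experiment '%s'; valid ids: %s", experiment_id,
                 paste(experiment_ids(), collapse = ", ")))
  }
  dir <- file.path(out_dir, experiment_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(experiment = experiment_id, seed = seed,
              n_iterations = n_iterations,
              package_version = as.character(utils::packageVersion("ernasim")))
  tables <- list()

  if (experiment_id == "waveform_spiking") {
    cohort <- generate_cohort(cohort_config(style = "spiking", seed = seed))
    tab <- erna_firing_table(cohort$recordings)
    st <- waveform_spiking_stats(tab)
    utils::write.csv(tab, file.path(dir, "site_stats.csv"),
                     row.names = FALSE)
    summary <- list(
      across_amplitude = st$across$amplitude_vs_firing[c("slope", "se", "t",
                                                         "p_bonferroni")],
      across_p2 = st$across$p2_vs_trough[c("slope", "se", "t",
                                           "p_bonferroni")],
      within_amplitude = st$within$amplitude_vs_firing[c("mean_rho", "t",
                                                         "p_bonferroni")],
      within_p2 = st$within$p2_vs_trough[c("mean_rho", "t",
                                           "p_bonferroni")])
    jsonlite::write_json(summary, file.path(dir, "stats_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    tables$site_stats <- tab
    tables$stats <- summary
  } else if (experiment_id == "peak_dynamics_cohort") {
    cohort <- generate_cohort(cohort_config(style = "dynamics",
                                            frequencies = 100,
                                            seed = seed))
    dyn <- cohort_dynamics(cohort)
    utils::write.csv(dyn, file.path(dir, "dynamics.csv"), row.names = FALSE)
    rho <- spearman_rho(dyn$p1_ratio, dyn$p2_ratio)
    summary <- list(mean_p1_ratio = mean(dyn$p1_ratio),
                    mean_p2_ratio = mean(dyn$p2_ratio),
                    rho_p1_vs_p2 = rho, n = nrow(dyn))
    jsonlite::write_json(summary, file.path(dir, "stats_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    tables$dynamics <- dyn
    tables$stats <- summary
  } else if (experiment_id == "circuit_scenarios") {
    conditions <- c("hfs_full", "lfs_20", "depressing_efferent",
                    "no_gpe_gpe")
    rows <- list()
    for (cond in conditions) {
      sc <- run_scenario(cond, n_iterations = n_iterations, seed = seed)
      rows[[cond]] <- data.frame(
        condition = cond,
        p1_ratio_mean = sc$p1_ratio_mean, p1_ratio_sd = sc$p1_ratio_sd,
        p2_ratio_mean = sc$p2_ratio_mean, p2_ratio_sd = sc$p2_ratio_sd,
        gpe_rate_on = sc$gpe_rate_on_mean,
        gpe_rate_off = sc$gpe_rate_off_mean)
      utils::write.csv(sc$mean_series,
                       file.path(dir, paste0("peak_series_", cond, ".csv")),
                       row.names = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(dir, "scenario_dynamics.csv"),
                     row.names = FALSE)
    tables$scenarios <- tab
  } else if (experiment_id == "frequency_sweep") {
    conditions <- c("lfs_10", "lfs_20", "lfs_30", "lfs_50", "hfs_full")
    rows <- lapply(conditions, function(cond) {
      sc <- run_scenario(cond, n_iterations = n_iterations, seed = seed)
      data.frame(condition = cond,
                 frequency = if (cond == "hfs_full") 100
                             else as.numeric(sub("lfs_", "", cond)),
                 p1_ratio_mean = sc$p1_ratio_mean,
                 p2_ratio_mean = sc$p2_ratio_mean)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(dir, "lfs_dynamics.csv"),
                     row.names = FALSE)
    tables$lfs <- tab
  }

  report <- list(experiment = experiment_id, seed = seed,
                 n_iterations = n_iterations,
                 provenance = config_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE)),
                 config = cfg, tables = tables, out_dir = dir)
  jsonlite::write_json(report[c("experiment", "seed", "n_iterations",
                                "provenance", "config")],
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  class(report) <- "run_report"
  report
}

#' Registry of acceptance targets and tolerances
#'
#' The single source of truth shared by [check_acceptance()] and the
#' acceptance script: for every reported quantity, the reference value,
#' comparison mode and tolerance.
#'
#' @return Data frame: `id`, `description`, `expected`, `tolerance`,
#'   `cmp`, `class`.
#' @export
acceptance_registry <- function() {
  data.frame(
    id = c("gpe_rate_off_hz", "gpe_rate_on_hz", "stn_rate_hz",
           "p1_dynamics_ratio", "p2_dynamics_ratio",
           "fidelity_cortico_stn_pct", "fidelity_gpe_class_pct",
           "fidelity_stn_efferent_pct"),
    description = c(
      "GPe mean rate, stimulation off (Hz)",
      "GPe mean rate during 100 Hz train (Hz)",
      "STN Poisson source rate (Hz)",
      "cohort-mean P1 40-45/first ratio",
      "cohort-mean P2 40-45/first ratio",
      "cortico-STN steady-state fidelity (%)",
      "GPe-class steady-state fidelity (%)",
      "STN-efferent steady-state fidelity (%)"),
    expected = c(40.5, 100, 39.9, 0.765, 1.395, 10, 65, 80),
    tolerance = c(4, 10, 1, 0.05, 0.07, 1, 1, 1),
    cmp = "eq",
    class = c("stochastic", "stochastic", "stochastic", "stochastic",
              "stochastic", "deterministic", "deterministic",
              "deterministic"),
    stringsAsFactors = FALSE)
}

#' Check reported values against the acceptance registry
#'
#' @param values named list or vector of measured values (names = target
#'   ids).
#' @param registry a registry data frame ([acceptance_registry()]).
#' @return Data frame: registry columns plus `value`, `pass` (`NA` when a
#'   target was not evaluated). A zero tolerance on a stochastic target is
#'   flagged as misconfigured.
#' @export
check_acceptance <- function(values, registry = acceptance_registry()) {
  bad <- registry$class == "stochastic" & registry$tolerance <= 0
  if (any(bad)) {
    stop(sprintf("misconfigured registry: zero tolerance on stochastic target(s) %s",
                 paste(registry$id[bad], collapse = ", ")))
  }
  registry$value <- vapply(registry$id, function(id) {
    v <- values[[id]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  registry$pass <- ifelse(
    is.na(registry$value), NA,
    abs(registry$value - registry$expected) <= registry$tolerance)
  registry
}
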