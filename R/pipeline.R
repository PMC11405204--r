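check_keys <- function(lst, allowed, where) {
  extra <- setdiff(names(lst), allowed)
  if (length(extra))
    abort(sprintf("unknown key(s) in %s: %s", where,
                  paste(extra, collapse = ", ")))
  lst
}

#' Read a run configuration from YAML
#'
#' A scenario file mirrors the [well_config()] / [treatment_design()] fields
#' plus stage parameters. Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_scenario.yaml",
#'                                    package = "seiznet"))
#' cfg$design$n_treated_wells
#' @export
read_run_config <- function(path) {
  validate_mea_config(yaml::read_yaml(path))
}

default_mea_config <- function() {
  list(seed = 1L,
       well = list(n_electrodes = 64, duration = 300, base_rate = 2,
                   burst_rate = 6, burst_duration = 0.3, burst_gain = 5,
                   coupling_kind = "paired", coupling_n_pairs = 16,
                   coupling_frac = 0.05, coupling_weight = 0.2),
       design = list(n_days = 3, rate_multipliers = c(1, 1.9, 2.5),
                     coupling_boost = 3, n_treated_wells = 9,
                     n_control_wells = 9),
       params = list(bin_width = 0.05, burst_frac_active = 0.25,
                     burst_rate_sd = 3, z_min = 0.80))
}

validate_mea_config <- function(config) {
  def <- default_mea_config()
  check_keys(config, names(def), "config")
  for (sec in c("well", "design", "params")) {
    if (!is.null(config[[sec]]))
      check_keys(config[[sec]], names(def[[sec]]), sec)
    def[[sec]] <- utils::modifyList(def[[sec]], config[[sec]] %||% list())
  }
  if (!is.null(config$seed)) def$seed <- config$seed
  def
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full MEA analysis pipeline on a synthetic scenario
#'
#' Simulates a treatment course, then for every well and day: writes the
#' spike list, bins counts, detects population bursts, computes
#' burst-excluded functional connectivity; per well, embeds the
#' connectivity trajectory; finally compares treated versus control wells
#' (normalized firing rate, strong-edge count, final-day trajectory
#' distance) and writes all artifacts plus a run manifest.
#'
#' @param config Config list (see [read_run_config()]) or a YAML path;
#'   missing entries take package defaults.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with `course`, `trajectories`, `mfr`, `stats`
#'   and `manifest`.
#' @export
run_mea_pipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_mea_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  set.seed(cfg$seed)
  w <- cfg$well
  coupling <- switch(w$coupling_kind,
    paired = paired_coupling(w$n_electrodes, w$coupling_n_pairs,
                             w$coupling_weight),
    directed = random_coupling(w$n_electrodes, w$coupling_frac,
                               w$coupling_weight),
    none = NULL,
    abort("coupling_kind must be 'paired', 'directed' or 'none'"))
  well <- well_config(w$n_electrodes, w$duration, w$base_rate, coupling,
                      w$burst_rate, w$burst_duration, w$burst_gain)
  design <- do.call(treatment_design, cfg$design)
  course <- simulate_treatment_course(well, design, seed = cfg$seed)

  p <- cfg$params
  course <- course %>%
    mutate(
      spike_csv = purrr::map2_chr(.data$trains, paste0(.data$well, "_day",
                                                       .data$day),
        function(tr, tag) {
          path <- file.path(outdir, paste0("spikes_", tag, ".csv"))
          write_spike_csv(tr, path)
          path
        }),
      binned = purrr::map(.data$trains, bin_spike_counts, width = p$bin_width),
      mask = purrr::map(.data$binned, detect_population_bursts,
                        frac_active = p$burst_frac_active,
                        rate_sd = p$burst_rate_sd),
      fc = purrr::map2(.data$binned, .data$mask, pairwise_fc),
      mfr = purrr::map(.data$trains, mean_firing_rate),
      n_strong_edges = purrr::map_int(
        .data$fc, ~ nrow(threshold_network(.x, p$z_min)$edges)))
  purrr::pwalk(course[, c("fc", "well", "day")], function(fc, well, day) {
    write_fc_long_csv(fc, file.path(outdir,
                                    sprintf("fc_%s_day%d.csv", well, day)))
  })

  traj <- course %>%
    group_by(.data$well, .data$group) %>%
    summarise(trajectory = list(embed_well(.data$fc, .data$day)),
              .groups = "drop")
  write_trajectory_csv(traj, file.path(outdir, "trajectories.csv"))

  last_day <- design$n_days - 1L
  norm_one_well <- function(mfr, day)
    purrr::map_dbl(mfr, function(m) normalize_mfr(m, mfr[[match(0, day)]])$ratio)
  mfr_tbl <- course %>%
    group_by(.data$well) %>%
    mutate(norm_mfr = norm_one_well(.data$mfr, .data$day)) %>%
    ungroup() %>%
    select("well", "group", "day", "norm_mfr", "n_strong_edges")

  pull_last <- function(tbl, col, grp)
    tbl[tbl$day == last_day & tbl$group == grp, ][[col]]
  dist_last <- traj %>%
    mutate(d = purrr::map_dbl(.data$trajectory,
                              ~ .x$distances[length(.x$distances)]))
  safe_t <- function(x, y, label) {
    if (length(x) < 2 || length(y) < 2) {
      warn(sprintf("'%s': fewer than 2 wells per group; test skipped",
                   label))
      res <- new_stat_result(NA_real_, NA_real_, NA_real_, mean(x) - mean(y),
                             NA_real_, NA_real_, NA_real_,
                             "two-sample (pooled)", degenerate = TRUE)
    } else {
      res <- two_sample_t(x, y)
    }
    mutate(res, comparison = label)
  }
  stats_tbl <- dplyr::bind_rows(
    safe_t(pull_last(mfr_tbl, "norm_mfr", "treated"),
           pull_last(mfr_tbl, "norm_mfr", "control"),
           sprintf("normalized MFR day %d", last_day)),
    safe_t(pull_last(mfr_tbl, "n_strong_edges", "treated"),
           pull_last(mfr_tbl, "n_strong_edges", "control"),
           sprintf("strong edges day %d", last_day)),
    safe_t(dist_last$d[dist_last$group == "treated"],
           dist_last$d[dist_last$group == "control"],
           sprintf("trajectory distance day %d", last_day)))
  utils::write.csv(
    data.frame(comparison = stats_tbl$comparison, t = stats_tbl$statistic,
               df = stats_tbl$df, p = stats_tbl$p_value,
               d = stats_tbl$cohens_d, ci_lo = stats_tbl$conf_low,
               ci_hi = stats_tbl$conf_high, test_kind = stats_tbl$method),
    file.path(outdir, "stats.csv"), row.names = FALSE, quote = FALSE)

  manifest <- list(pipeline = "mea", package = "seiznet",
                   version = as.character(utils::packageVersion("seiznet")),
                   seed = cfg$seed, well = cfg$well, design = cfg$design,
                   params = cfg$params,
                   n_wells = length(unique(course$well)),
                   n_recordings = nrow(course),
                   n_spikes_total = sum(purrr::map_int(course$trains, nrow)),
                   n_trajectories = nrow(traj))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(course = course, trajectories = traj, mfr = mfr_tbl,
                 stats = stats_tbl, manifest = manifest))
}

default_iceeg_config <- function() {
  list(seed = 1L,
       cohort = list(n_patients = 5, n_pairs_per_class = 6,
                     n_samples = 10000, fs = 1000, kappa_sp = 4,
                     kappa_control = 1),
       params = list(band = c(70, 90), detrend_window = 1,
                     line_freqs = c(60, 120), lowpass_cutoff = 150))
}

#' Run the icEEG phase-locking pipeline on a synthetic cohort
#'
#' Simulates phase-coupled contact pairs for a cohort (stronger coupling for
#' SOZ-SP than SOZ-control pairs), computes per-pair PLV through the full
#' preprocessing chain, and performs the paired across-patient comparison.
#' Writes the PLV table, patient class means, test result and a manifest.
#'
#' @param config Config list with optional `seed`, `cohort` and `params`
#'   sections (see Details in [run_mea_pipeline()]); or a YAML path.
#' @param outdir Output directory.
#' @param seed Optional override of the config seed.
#' @return Invisibly, a list with `plc`, `comparison` and `manifest`.
#' @export
run_iceeg_pipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_iceeg_config()
  check_keys(config, names(def), "config")
  for (sec in c("cohort", "params")) {
    if (!is.null(config[[sec]]))
      check_keys(config[[sec]], names(def[[sec]]), sec)
    def[[sec]] <- utils::modifyList(def[[sec]], config[[sec]] %||% list())
  }
  if (!is.null(config$seed)) def$seed <- config$seed
  if (!is.null(seed)) def$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  co <- def$cohort
  cohort <- simulate_iceeg_cohort(co$n_patients, co$n_pairs_per_class,
                                  co$n_samples, co$fs, def$params$band,
                                  co$kappa_sp, co$kappa_control,
                                  seed = def$seed)
  plc <- compute_plc(cohort, band = def$params$band,
                     detrend_window = def$params$detrend_window,
                     line_freqs = def$params$line_freqs,
                     lowpass_cutoff = def$params$lowpass_cutoff)
  write_plc_csv(plc, file.path(outdir, "plc.csv"))
  cmp <- compare_soz_pairs(plc)
  utils::write.csv(as.data.frame(cmp$patient_means),
                   file.path(outdir, "patient_means.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(comparison = "SOZ-SP vs SOZ-control PLV",
               t = cmp$test$statistic, df = cmp$test$df, p = cmp$test$p_value,
               d = cmp$test$cohens_d, ci_lo = cmp$test$conf_low,
               ci_hi = cmp$test$conf_high, test_kind = cmp$test$method),
    file.path(outdir, "stats.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(pipeline = "iceeg", package = "seiznet",
                   version = as.character(utils::packageVersion("seiznet")),
                   seed = def$seed, cohort = def$cohort, params = def$params,
                   n_pairs = nrow(plc),
                   n_patients_tested = nrow(cmp$patient_means))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(plc = plc, comparison = cmp, manifest = manifest))
}
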