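#' Detect multi-unit spikes by robust threshold crossing
#'
#' Classic MEA convention: the per-channel noise level is estimated robustly
#' as `median(|x|) / 0.6745` (the MAD-based SD of a Gaussian), the threshold
#' is `k` times that, and threshold crossings of either polarity are events.
#' Contiguous supra-threshold runs are reduced to their absolute peak;
#' events closer than the dead time are merged, keeping the larger absolute
#' peak. The spike time is the peak sample divided by the sampling rate.
#'
#' The detector requires a conditioned input (stage `"filtered"` or
#' `"zscored"`): thresholds on raw traces would chase drift and line noise.
#' Because the threshold scales with the trace, detection is invariant to
#' positive rescaling of the input.
#'
#' @param rec A conditioned [voltage_recording()].
#' @param k Threshold multiplier on the robust noise SD.
#' @param dead_time Minimum separation between events in seconds.
#' @return A `spike_trains` tibble with provenance `"detected"`.
#' @export
detect_spikes <- function(rec, k = 5.5, dead_time = 0.001) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (rec$stage == "raw")
    abort("detect_spikes requires a conditioned recording (stage 'filtered' or 'zscored'), not raw voltage")
  dead_n <- dead_time * rec$fs
  res <- purrr::map(seq_len(nrow(rec$samples)), function(ch) {
    x <- rec$samples[ch, ]
    noise_sd <- stats::median(abs(x)) / 0.6745
    if (noise_sd == 0) return(integer(0))
    thr <- k * noise_sd
    over <- abs(x) > thr
    if (!any(over)) return(integer(0))
    idx <- which(over)
    run_id <- cumsum(c(1L, diff(idx) > 1L))
    peaks <- vapply(split(idx, run_id),
                    function(ii) ii[which.max(abs(x[ii]))], integer(1))
    # merge events closer than the dead time, keeping the larger peak
    merged <- peaks[1]
    for (p in peaks[-1]) {
      last <- merged[length(merged)]
      if (p - last < dead_n) {
        if (abs(x[p]) > abs(x[last])) merged[length(merged)] <- p
      } else merged <- c(merged, p)
    }
    merged
  })
  df <- tibble(
    electrode = rep(seq_along(res), lengths(res)),
    time_s = (unlist(res) - 1) / rec$fs)
  if (nrow(df) == 0) df <- tibble(electrode = integer(0), time_s = numeric(0))
  new_spike_trains(df, duration = ncol(rec$samples) / rec$fs,
                   n_electrodes = nrow(rec$samples), provenance = "detected")
}

#' Round-trip validation of the conditioning and detection chain
#'
#' Simulates ground-truth spike trains, synthesizes raw voltage with the
#' template embedded at each spike time, runs the full conditioning chain
#' (downsample, band-pass, notch cascade, z-score) and the threshold
#' detector, and scores detections against the ground truth. A detection
#' within `match_tol` of a true spike is a hit. Scoring is restricted to
#' spikes and detections inside `[settle, duration - settle]`: the band-pass
#' low corner (0.1 Hz) leaves a settle transient of a couple of seconds at
#' the record edges that no finite recording can determine.
#'
#' Zero-phase conditioning is used so detected peak times are not shifted by
#' filter group delay.
#'
#' @param n_electrodes,duration,base_rate Ground-truth well parameters.
#' @param tmpl A [spike_template()]; its `amp_uV / noise_sd` sets the raw
#'   signal-to-noise ratio.
#' @param fs Acquisition rate in Hz.
#' @param k Detector threshold multiplier.
#' @param dead_time Detector dead time in seconds.
#' @param match_tol Matching tolerance in seconds.
#' @param settle Edge margin excluded from scoring, in seconds.
#' @param seed Seed for trains and noise.
#' @return One-row tibble: `recall`, `precision`, `max_abs_dt_s`, `n_true`,
#'   `n_detected`.
#' @export
spike_detection_roundtrip <- function(n_electrodes = 8, duration = 20,
                                      base_rate = 1,
                                      tmpl = spike_template(amp_uV = 80,
                                                            noise_sd = 10),
                                      fs = 12500, k = 5.5,
                                      dead_time = 0.003,
                                      match_tol = 0.001, settle = 2,
                                      seed = 1) {
  cfg <- well_config(n_electrodes, duration, base_rate, burst_rate = 0,
                     seed = seed)
  st <- simulate_spike_trains(cfg)
  rec <- simulate_voltage(st, tmpl, fs = fs, seed = seed + 1)
  cond <- condition_recording(rec, zero_phase = TRUE)
  det <- detect_spikes(cond, k = k, dead_time = dead_time)
  inside <- function(t) t >= settle & t <= duration - settle
  per <- purrr::map(seq_len(n_electrodes), function(ch) {
    tt <- st$time_s[st$electrode == ch & inside(st$time_s)]
    dd <- det$time_s[det$electrode == ch & inside(det$time_s)]
    hit <- vapply(tt, function(t) length(dd) > 0 &&
                    min(abs(dd - t)) <= match_tol, logical(1))
    err <- vapply(tt[hit], function(t) min(abs(dd - t)), numeric(1))
    list(n_true = length(tt), n_det = length(dd), tp = sum(hit),
         max_err = if (length(err)) max(err) else 0)
  })
  n_true <- sum(purrr::map_dbl(per, "n_true"))
  n_det <- sum(purrr::map_dbl(per, "n_det"))
  tp <- sum(purrr::map_dbl(per, "tp"))
  tibble(recall = tp / n_true, precision = tp / n_det,
         max_abs_dt_s = max(purrr::map_dbl(per, "max_err")),
         n_true = n_true, n_detected = n_det)
}

#' Mean firing rate of a well
#'
#' Per-electrode spike count divided by duration, and the well mean over all
#' electrodes (silent electrodes count as 0 Hz).
#'
#' @param trains A `spike_trains` object.
#' @return An `mfr_summary`: list with `per_electrode` (tibble `electrode`,
#'   `rate_hz`), `well_mean_hz` and `duration`.
#' @export
mean_firing_rate <- function(trains) {
  stopifnot(inherits(trains, "spike_trains"))
  dur <- train_duration(trains)
  stopifnot(dur > 0)
  counts <- tabulate(trains$electrode, nbins = n_electrodes(trains))
  per <- tibble(electrode = seq_len(n_electrodes(trains)),
                rate_hz = counts / dur)
  structure(list(per_electrode = per, well_mean_hz = mean(per$rate_hz),
                 duration = dur),
            class = "mfr_summary")
}

#' @export
print.mfr_summary <- function(x, ...) {
  cat(sprintf("<mfr_summary> %d electrodes, well mean %.3f Hz over %.1f s\n",
              nrow(x$per_electrode), x$well_mean_hz, x$duration))
  invisible(x)
}

#' @export
tidy.mfr_summary <- function(x, ...) x$per_electrode

#' @export
glance.mfr_summary <- function(x, ...) {
  tibble(well_mean_hz = x$well_mean_hz,
         n_electrodes = nrow(x$per_electrode), duration = x$duration)
}

#' Normalize a firing-rate summary to a baseline
#'
#' Ratio of well-mean firing rates, the standard way of expressing
#' treatment-induced excitability changes relative to the pre-treatment day.
#' A zero baseline makes the ratio undefined; it is flagged (`defined =
#' FALSE`, ratio `NA`) rather than silently divided.
#'
#' @param day,baseline `mfr_summary` objects.
#' @return A one-row tibble with columns `ratio` and `defined`.
#' @export
normalize_mfr <- function(day, baseline) {
  stopifnot(inherits(day, "mfr_summary"), inherits(baseline, "mfr_summary"))
  if (baseline$well_mean_hz == 0) {
    warn("baseline well-mean rate is 0; normalized MFR undefined")
    return(tibble(ratio = NA_real_, defined = FALSE))
  }
  tibble(ratio = day$well_mean_hz / baseline$well_mean_hz, defined = TRUE)
}

#' Detect population bursts in bin space
#'
#' A bin is a burst bin when the population spike count exceeds its mean by
#' `rate_sd` standard deviations AND at least `frac_active` of electrodes
#' fired in the bin. Detection operates directly at the functional-
#' connectivity bin resolution because its purpose is to mask bins from the
#' correlation estimate; runs of burst bins are merged into intervals.
#'
#' @param binned A [bin_spike_counts()] result.
#' @param frac_active Minimum fraction of simultaneously active electrodes.
#' @param rate_sd Population-rate threshold in SD units.
#' @return A `burst_mask`: list with `intervals` (tibble `start_s`, `end_s`),
#'   `flags` (logical per bin) and `params`.
#' @export
detect_population_bursts <- function(binned, frac_active = 0.25,
                                     rate_sd = 3) {
  stopifnot(inherits(binned, "binned_spikes"))
  pop <- colSums(binned$counts)
  active <- colMeans(binned$counts > 0)
  thr <- mean(pop) + rate_sd * stats::sd(pop)
  flags <- pop > thr & active >= frac_active
  if (all(binned$counts == 0)) flags[] <- FALSE
  structure(list(intervals = runs_to_intervals(flags, binned$width),
                 flags = flags,
                 params = list(frac_active = frac_active, rate_sd = rate_sd)),
            class = "burst_mask")
}

#' @export
print.burst_mask <- function(x, ...) {
  cat(sprintf("<burst_mask> %d interval(s), %d/%d burst bins\n",
              nrow(x$intervals), sum(x$flags), length(x$flags)))
  invisible(x)
}

#' Write burst intervals as CSV
#'
#' Two-column CSV with header `start_s,end_s`.
#'
#' @param mask A `burst_mask`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_burst_csv <- function(mask, path) {
  stopifnot(inherits(mask, "burst_mask"))
  utils::write.csv(as.data.frame(mask$intervals), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
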