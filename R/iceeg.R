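#' Local detrending by running-mean subtraction
#'
#' Removes slow fluctuations by subtracting a centered moving average of
#' `window` seconds; near the edges the window shrinks to the available
#' samples, so no samples are lost.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate in Hz.
#' @param window Trend window in seconds (> 0, shorter than the epoch).
#' @return The detrended series.
#' @export
local_detrend <- function(x, fs, window = 1) {
  if (window <= 0) abort("window must be > 0")
  n <- length(x)
  if (window * fs >= 2 * n) abort("window must be shorter than the epoch")
  h <- max(1L, round(window * fs / 2))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  trend <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  x - trend
}

#' Remove line noise by sinusoidal regression
#'
#' Least-squares fit of a sine/cosine pair at each target frequency over the
#' whole epoch; the fitted components are subtracted. Over epochs much
#' longer than a line-noise cycle the regressors are nearly orthogonal to
#' off-frequency activity, so physiological content is preserved.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate in Hz.
#' @param freqs Frequencies to remove (Hz, default 60 and 120).
#' @return The residual series.
#' @export
regress_line_noise <- function(x, fs, freqs = c(60, 120)) {
  stopifnot(all(freqs < fs / 2))
  if (length(x) < fs / min(freqs))
    abort("epoch shorter than one cycle of the lowest target frequency")
  t <- (seq_along(x) - 1) / fs
  X <- do.call(cbind, lapply(freqs, function(f)
    cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))))
  fit <- stats::.lm.fit(cbind(1, X), x)
  fit$residuals + mean(x)  # keep the mean; only oscillatory parts removed
}

#' Equiripple FIR designs for the high-gamma pipeline
#'
#' Parks-McClellan (Remez-exchange) linear-phase designs via
#' [signal::remez()]. `design_fir_lowpass()` is the anti-harmonic low-pass
#' (even order 180, passband up to `cutoff`); `design_fir_bandpass()` the
#' high-gamma band-pass (even order 390, passband `band`). Even orders give
#' type-1 (odd-length, symmetric) filters whose group delay is an integer
#' number of samples.
#'
#' @param fs Sampling rate in Hz.
#' @param cutoff Low-pass passband edge in Hz.
#' @param band Band-pass passband `c(low, high)` in Hz.
#' @param trans Transition width in Hz.
#' @param order Filter order (even).
#' @return Numeric coefficient vector of length `order + 1`.
#' @export
design_fir_lowpass <- function(fs, cutoff = 150, trans = 10, order = 180) {
  if (order %% 2 != 0) abort("order must be even (type-1 FIR)")
  ny <- fs / 2
  if (cutoff + trans >= ny)
    abort(sprintf("low-pass spec infeasible: edge %g + transition %g >= Nyquist %g",
                  cutoff, trans, ny))
  remez_checked(order, c(0, cutoff, cutoff + trans, ny) / ny, c(1, 1, 0, 0),
                sprintf("low-pass order %d, edge %g Hz at fs %g", order,
                        cutoff, fs))
}

# signal::remez fails with an uninformative code when the equiripple
# exchange cannot meet a spec; re-raise with the offending design.
remez_checked <- function(order, f, a, what) {
  tryCatch(signal::remez(order, f, a),
           error = function(e)
             abort(sprintf("FIR design infeasible (%s): %s", what,
                           conditionMessage(e))))
}

#' @rdname design_fir_lowpass
#' @export
design_fir_bandpass <- function(fs, band = c(70, 90), trans = 10,
                                order = 390) {
  if (order %% 2 != 0) abort("order must be even (type-1 FIR)")
  ny <- fs / 2
  if (band[1] - trans <= 0 || band[2] + trans >= ny)
    abort(sprintf("band-pass spec infeasible at fs = %g: band %g-%g with transition %g",
                  fs, band[1], band[2], trans))
  remez_checked(order,
                c(0, band[1] - trans, band[1], band[2], band[2] + trans, ny) / ny,
                c(0, 0, 1, 1, 0, 0),
                sprintf("band-pass order %d, band %g-%g Hz at fs %g", order,
                        band[1], band[2], fs))
}

# Zero-delay application of a symmetric odd-length FIR: full convolution,
# centered segment extracted (the linear-phase delay of order/2 samples is
# compensated exactly).
fir_apply <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  L <- (length(h) - 1) / 2
  y <- stats::convolve(x, rev(h), type = "open")
  y[(L + 1):(L + length(x))]
}

#' Apply the high-gamma FIR chain
#'
#' Low-pass (removing residual line harmonics and high-frequency noise)
#' followed by the 70-90 Hz high-gamma band-pass, both equiripple
#' linear-phase designs applied with exact group-delay compensation.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate in Hz (> 180).
#' @param lowpass_cutoff Low-pass passband edge (Hz).
#' @param band High-gamma passband (Hz).
#' @param trans Transition width (Hz).
#' @return The band-limited series.
#' @export
fir_filters <- function(x, fs, lowpass_cutoff = 150, band = c(70, 90),
                        trans = 10) {
  stopifnot(fs / 2 > band[2])
  lp <- design_fir_lowpass(fs, lowpass_cutoff, trans)
  bp <- design_fir_bandpass(fs, band, trans)
  fir_apply(fir_apply(x, lp), bp)
}

# Analytic signal via the FFT construction (positive frequencies doubled,
# negative zeroed).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value of two band-limited signals
#'
#' Instantaneous phases are taken from the analytic signals (Hilbert
#' construction) and the PLV is the magnitude of the mean unit phasor of
#' their difference: 1 for perfectly phase-locked signals, near 0 for
#' independent ones. Invariant to amplitude scaling and to any constant
#' phase offset of either input.
#'
#' @param x,y Equal-length numeric vectors, band-limited.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (all(x == 0) || all(y == 0))
    abort("all-zero input: instantaneous phase undefined")
  px <- Arg(analytic_signal(x))
  py <- Arg(analytic_signal(y))
  Mod(mean(exp(1i * (px - py))))
}

#' Phase-locking connectivity table for an icEEG cohort
#'
#' Runs the full per-epoch pipeline — local detrend, line-noise regression,
#' low-pass FIR, high-gamma band-pass FIR, Hilbert phases — on every contact
#' pair and computes the PLV. If an `epoch` column is present, PLVs are
#' computed per epoch and averaged within pair.
#'
#' @param cohort Tibble with columns `patient`, `pair`, `class`
#'   (`"SOZ-SP"` or `"SOZ-control"`), list columns `x`, `y`, and `fs`
#'   (see [simulate_iceeg_cohort()]).
#' @param band High-gamma passband (Hz).
#' @param detrend_window Detrend window (s).
#' @param line_freqs Frequencies for the line-noise regression (Hz).
#' @param lowpass_cutoff Low-pass passband edge (Hz).
#' @return A `plc_result` tibble: `patient`, `pair`, `class`, `plv`.
#' @export
compute_plc <- function(cohort, band = c(70, 90), detrend_window = 1,
                        line_freqs = c(60, 120), lowpass_cutoff = 150) {
  stopifnot(all(c("patient", "pair", "class", "x", "y", "fs") %in%
                  names(cohort)))
  bad <- setdiff(unique(cohort$class), c("SOZ-SP", "SOZ-control"))
  if (length(bad))
    abort(paste("unknown pair class:", paste(bad, collapse = ", ")))
  pre <- function(sig, fs) {
    sig %>%
      local_detrend(fs, detrend_window) %>%
      regress_line_noise(fs, line_freqs) %>%
      fir_filters(fs, lowpass_cutoff, band)
  }
  out <- cohort
  out$plv <- purrr::pmap_dbl(cohort[, c("x", "y", "fs")],
                             function(x, y, fs) plv(pre(x, fs), pre(y, fs)))
  out <- out[, c("patient", "pair", "class",
                 intersect("epoch", names(out)), "plv")]
  if ("epoch" %in% names(out))
    out <- out %>%
      group_by(.data$patient, .data$pair, .data$class) %>%
      summarise(plv = mean(.data$plv), .groups = "drop")
  class(out) <- c("plc_result", class(tibble()))
  out
}

#' Compare SOZ-SP and SOZ-control synchronization across patients
#'
#' Averages PLV per patient and pair class, then applies a paired t-test
#' across patients (SOZ-SP mean vs SOZ-control mean). Patients lacking one
#' of the classes are excluded with a warning; at least two complete
#' patients are required.
#'
#' @param results A `plc_result` tibble (see [compute_plc()]), or any tibble
#'   with `patient`, `class`, `plv`.
#' @return A `soz_comparison`: list with `patient_means` (tibble `patient`,
#'   `plv_soz_sp`, `plv_soz_control`) and `test` (paired [stat_result]).
#' @export
compare_soz_pairs <- function(results) {
  stopifnot(all(c("patient", "class", "plv") %in% names(results)))
  wide <- results %>%
    group_by(.data$patient, .data$class) %>%
    summarise(plv = mean(.data$plv), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "class", values_from = "plv")
  missing <- is.na(wide[["SOZ-SP"]]) | is.na(wide[["SOZ-control"]])
  if (is.null(wide[["SOZ-SP"]]) || is.null(wide[["SOZ-control"]]))
    abort("need both SOZ-SP and SOZ-control pairs")
  if (any(missing)) {
    warn(sprintf("excluding %d patient(s) missing a pair class",
                 sum(missing)))
    wide <- wide[!missing, ]
  }
  if (nrow(wide) < 2)
    abort("need at least 2 patients with both pair classes")
  pm <- tibble(patient = wide$patient,
               plv_soz_sp = wide[["SOZ-SP"]],
               plv_soz_control = wide[["SOZ-control"]])
  structure(list(patient_means = pm,
                 test = paired_t(pm$plv_soz_sp, pm$plv_soz_control)),
            class = "soz_comparison")
}

#' @export
print.soz_comparison <- function(x, ...) {
  cat(sprintf("<soz_comparison> %d patients: SOZ-SP %.3f vs SOZ-control %.3f, t(%d) = %.2f, p = %.4f\n",
              nrow(x$patient_means), mean(x$patient_means$plv_soz_sp),
              mean(x$patient_means$plv_soz_control), x$test$df,
              x$test$statistic, x$test$p_value))
  invisible(x)
}

#' @export
tidy.soz_comparison <- function(x, ...) x$patient_means

#' @export
glance.soz_comparison <- function(x, ...) x$test

#' Write a PLC table as CSV
#'
#' Long CSV with header `patient,pair,class,plv`.
#'
#' @param results A `plc_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_plc_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
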