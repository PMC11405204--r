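# Butterworth designs are realized as cascaded second-order sections
# (biquads): direct-form transfer-function polynomials at order 20 are
# numerically explosive, and a biquad cascade is the standard stable
# realization.  Design path: analog prototype poles -> frequency transform
# (low/high/band-pass/band-stop) -> bilinear map -> conjugate-pair biquads,
# each magnitude-normalized at the band's reference frequency.

butter_sos <- function(order, w, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  stopifnot(all(w > 0), all(w < 1))
  if (type %in% c("pass", "stop")) {
    stopifnot(length(w) == 2, w[1] < w[2])
    if (order %% 2 != 0) abort("band filters need an even overall order")
    n <- order / 2
  } else {
    stopifnot(length(w) == 1)
    n <- order
  }
  if (n %% 2 != 0)
    abort("prototype order must be even (real poles unsupported)")
  # analog Butterworth prototype poles with positive imaginary part
  k <- seq_len(n / 2)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  wa <- tan(pi * w / 2)  # bilinear prewarp
  if (type == "low") {
    poles <- wa * p_proto
    num <- c(1, 2, 1)            # two zeros at z = -1 per biquad
    ref_w <- 0
  } else if (type == "high") {
    poles <- wa / p_proto
    num <- c(1, -2, 1)           # two zeros at z = +1 per biquad
    ref_w <- pi
  } else {
    bw <- wa[2] - wa[1]
    w0 <- sqrt(wa[1] * wa[2])
    w0d <- 2 * atan(w0)
    if (type == "pass") {
      # each prototype pole maps to one pole pair near the upper band edge
      # and one near the lower; zeros are paired with the nearest cluster
      # (z = -1 with the upper-edge poles, z = +1 with the lower-edge) so
      # that no section carries a near-unit-circle pole without its
      # cancelling zero -- the same pairing rule standard zp2sos uses
      disc <- sqrt(as.complex((bw * p_proto)^2 - 4 * w0^2))
      poles <- c((bw * p_proto + disc) / 2, (bw * p_proto - disc) / 2)
      num <- NULL
      # upper-edge poles (|s| > w0) take the z = -1 zeros, lower-edge poles
      # the z = +1 zeros (magnitude test is robust to the sqrt branch)
      num_per_pole <- t(vapply(poles, function(s) {
        if (Mod(s) > w0) c(1, 2, 1) else c(1, -2, 1)
      }, numeric(3)))
      ref_w <- w0d
    } else {
      disc <- sqrt(as.complex(bw^2 - 4 * p_proto^2 * w0^2))
      poles <- c((bw + disc) / (2 * p_proto), (bw - disc) / (2 * p_proto))
      num <- c(1, -2 * cos(w0d), 1)  # zeros at exp(+-i w0d) per biquad
      ref_w <- 0
    }
  }
  zd <- (1 + poles) / (1 - poles)  # bilinear map of the analog poles
  if (is.null(num)) {
    nums <- num_per_pole
  } else {
    nums <- matrix(rep(num, length(zd)), ncol = 3, byrow = TRUE)
  }
  sos <- t(vapply(seq_along(zd), function(i) {
    p <- zd[i]
    den <- c(1, -2 * Re(p), Mod(p)^2)
    s <- c(nums[i, ], den)
    h <- biquad_response(s, ref_w)
    s[1:3] <- s[1:3] / Mod(h)
    s
  }, numeric(6)))
  # run low-Q sections first, highest-Q (poles nearest the unit circle) last
  sos[order(sos[, 6]), , drop = FALSE]
}

biquad_response <- function(row, w) {
  z <- exp(-1i * w)
  (row[1] + row[2] * z + row[3] * z^2) / (row[4] + row[5] * z + row[6] * z^2)
}

sos_response <- function(sos, w) {
  vapply(w, function(wi) {
    Mod(Reduce(`*`, lapply(seq_len(nrow(sos)),
                           function(s) biquad_response(sos[s, ], wi))))
  }, numeric(1))
}

# Zero-phase filtering pads both ends by odd reflection (continuous value
# and slope at the joins) before the forward-backward pass, then trims.
# pad_len should cover a few time constants of the slowest pole, otherwise
# low-corner transients bleed seconds into the record edges.
apply_sos <- function(x, sos, zero_phase = FALSE, steady_init = TRUE,
                      pad_len = 0L) {
  if (zero_phase) {
    n <- length(x)
    p <- min(as.integer(pad_len), n - 1L)
    if (p > 0) {
      head_pad <- 2 * x[1] - x[(p + 1):2]
      tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
      x <- c(head_pad, x, tail_pad)
    }
    y <- sosfilt_core(sos, x, steady_init)
    y <- rev(sosfilt_core(sos, rev(y), steady_init))
    if (p > 0) y <- y[(p + 1):(p + n)]
  } else {
    y <- sosfilt_core(sos, x, steady_init)
  }
  if (!all(is.finite(y)))
    abort("filter realization produced non-finite output (unstable design)")
  y
}

filter_channels <- function(rec, sos, zero_phase, stage = "filtered",
                            pad_s = 0) {
  out <- rec
  out$samples <- t(apply(rec$samples, 1, apply_sos, sos = sos,
                         zero_phase = zero_phase,
                         pad_len = round(pad_s * rec$fs)))
  out$stage <- stage
  out
}

#' Analytic magnitude response of the package's filter designs
#'
#' Evaluates the designed transfer function directly (product of biquad
#' responses on the unit circle), independent of any time-domain filtering.
#' Useful for verifying that a realized filter matches its design.
#'
#' @param design A filter design as returned by [design_bandpass_mua()],
#'   [design_notch()] or [design_antialias()].
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Magnitude response (linear gain) at `f`.
#' @export
filter_response <- function(design, f, fs) {
  stopifnot(is.matrix(design), ncol(design) == 6)
  sos_response(design, 2 * pi * f / fs)
}

#' Filter designs used by the conditioning chain
#'
#' `design_bandpass_mua()` is the multi-unit-activity band-pass (Butterworth,
#' default 0.1-300 Hz, overall order 20). `design_notch()` is one band-stop
#' section of the line-noise cascade (Butterworth, order 4, stop edges
#' `f0 +- half_bw`). `design_antialias()` is the low-pass applied before
#' decimation (Butterworth order 8, cutoff `0.4 * target_fs`).
#'
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz.
#' @param order Overall filter order (band filters use an order/2 prototype).
#' @param f0 Notch center frequency in Hz.
#' @param half_bw Notch half bandwidth in Hz.
#' @param target_fs Output rate of the decimation the anti-alias filter
#'   protects.
#' @return A second-order-section matrix (rows `b0 b1 b2 a0 a1 a2`).
#' @export
design_bandpass_mua <- function(fs, low = 0.1, high = 300, order = 20) {
  stopifnot(low < high, high < fs / 2)
  butter_sos(order, c(low, high) / (fs / 2), "pass")
}

#' @rdname design_bandpass_mua
#' @export
design_notch <- function(fs, f0, order = 4, half_bw = 1) {
  stopifnot(f0 + half_bw < fs / 2, f0 - half_bw > 0)
  butter_sos(order, c(f0 - half_bw, f0 + half_bw) / (fs / 2), "stop")
}

#' @rdname design_bandpass_mua
#' @export
design_antialias <- function(fs, target_fs) {
  butter_sos(8, 0.4 * target_fs / (fs / 2), "low")
}

#' Downsample a voltage recording by an integer factor
#'
#' Applies the anti-alias low-pass of [design_antialias()] and keeps every
#' `fs / target_fs`-th sample. The output has `floor(n / factor)` samples per
#' channel.
#'
#' @param rec A [voltage_recording()].
#' @param target_fs Target sampling rate; `fs` must be an integer multiple.
#' @param zero_phase Filter forward-backward instead of causally.
#' @return The decimated `voltage_recording`.
#' @export
downsample <- function(rec, target_fs = 2500, zero_phase = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    abort("fs must be an integer multiple of target_fs")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  out <- filter_channels(rec, design_antialias(rec$fs, target_fs),
                         zero_phase, stage = rec$stage,
                         pad_s = 3 / (2 * pi * 0.4 * target_fs))
  n_out <- floor(ncol(rec$samples) / factor)
  out$samples <- out$samples[, seq(1L, by = factor, length.out = n_out),
                             drop = FALSE]
  out$fs <- target_fs
  out
}

#' Band-pass filter for multi-unit activity
#'
#' Butterworth band-pass (default 0.1-300 Hz, overall order 20) applied per
#' channel, realized as cascaded second-order sections for numerical
#' stability. Removes slow drift and DC offsets while retaining the
#' multi-unit spiking band.
#'
#' @inheritParams downsample
#' @inheritParams design_bandpass_mua
#' @return The filtered `voltage_recording` (stage `"filtered"`).
#' @export
bandpass_mua <- function(rec, low = 0.1, high = 300, order = 20,
                         zero_phase = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"))
  filter_channels(rec, design_bandpass_mua(rec$fs, low, high, order),
                  zero_phase, pad_s = 3 / (2 * pi * low))
}

#' Notch out mains interference and harmonics
#'
#' Cascade of narrow Butterworth band-stop filters (order 4, stop edges
#' within `half_bw` of each target frequency), by default at 60 Hz and its
#' first two harmonics.
#'
#' @inheritParams downsample
#' @param freqs Center frequencies in Hz; all must lie below Nyquist.
#' @inheritParams design_bandpass_mua
#' @return The filtered `voltage_recording` (stage `"filtered"`).
#' @export
notch_line <- function(rec, freqs = c(60, 120, 180), order = 4, half_bw = 1,
                       zero_phase = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (any(freqs >= rec$fs / 2))
    abort("notch frequencies must be below Nyquist")
  out <- rec
  for (f0 in freqs)
    out <- filter_channels(out, design_notch(rec$fs, f0, order, half_bw),
                           zero_phase, pad_s = 3 / (2 * pi * half_bw))
  out
}

#' Z-score each channel
#'
#' Centers and scales every channel to mean 0 and standard deviation 1,
#' using the population SD (divide by N) so the transform is an exact fixed
#' convention. Constant channels cannot be scaled and are set to all zeros
#' with a warning.
#'
#' @inheritParams downsample
#' @param sample_sd Use the sample SD (divide by N-1) instead.
#' @return The standardized `voltage_recording` (stage `"zscored"`).
#' @export
zscore_recording <- function(rec, sample_sd = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"), ncol(rec$samples) > 1)
  out <- rec
  n <- ncol(rec$samples)
  mu <- rowMeans(rec$samples)
  cen <- rec$samples - mu
  s <- sqrt(rowMeans(cen^2))
  if (sample_sd) s <- s * sqrt(n / (n - 1))
  flat <- s == 0
  if (any(flat)) {
    warn(sprintf("%d constant channel(s) set to zero", sum(flat)))
    s[flat] <- 1
    cen[flat, ] <- 0
  }
  out$samples <- cen / s
  out$stage <- "zscored"
  out
}

#' Full MEA conditioning chain
#'
#' Convenience wrapper running downsample (12.5 kHz to 2.5 kHz by default),
#' multi-unit band-pass, line-noise notch cascade, and per-channel
#' z-scoring, in that order.
#'
#' @inheritParams downsample
#' @param notch_freqs Line frequencies for [notch_line()].
#' @inheritParams design_bandpass_mua
#' @return A `voltage_recording` with stage `"zscored"`.
#' @export
condition_recording <- function(rec, target_fs = 2500, low = 0.1, high = 300,
                                order = 20, notch_freqs = c(60, 120, 180),
                                zero_phase = FALSE) {
  rec %>%
    downsample(target_fs, zero_phase = zero_phase) %>%
    bandpass_mua(low, high, order, zero_phase = zero_phase) %>%
    notch_line(notch_freqs, zero_phase = zero_phase) %>%
    zscore_recording()
}
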