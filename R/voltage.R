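#' Multichannel voltage recording
#'
#' Container for raw or conditioned extracellular voltage: a channels x
#' samples matrix with sampling rate, electrode grid geometry and a
#' processing-stage tag (`"raw"`, `"filtered"` or `"zscored"`).
#'
#' @param samples Numeric matrix, channels x samples (microvolts, or z-units
#'   after standardization).
#' @param fs Sampling rate in Hz.
#' @param electrodes Optional tibble with columns `electrode`, `row`, `col`
#'   giving grid positions; defaults to a near-square grid (8x8 for 64
#'   channels, 300 um pitch being the physical convention this mirrors).
#' @param stage Processing stage tag.
#' @return A `voltage_recording` object.
#' @export
voltage_recording <- function(samples, fs,
                              electrodes = NULL,
                              stage = c("raw", "filtered", "zscored")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(samples), fs > 0)
  n_ch <- nrow(samples)
  if (is.null(electrodes)) {
    ncol_grid <- ceiling(sqrt(n_ch))
    electrodes <- tibble(electrode = seq_len(n_ch),
                         row = (seq_len(n_ch) - 1L) %/% ncol_grid + 1L,
                         col = (seq_len(n_ch) - 1L) %% ncol_grid + 1L)
  }
  stopifnot(nrow(electrodes) == n_ch,
            !anyDuplicated(electrodes[, c("row", "col")]))
  structure(list(samples = samples, fs = fs, electrodes = electrodes,
                 stage = stage),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("<voltage_recording> %d channels x %d samples @ %g Hz (%.1f s), stage: %s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$stage))
  invisible(x)
}

#' Write / read a voltage recording as flat binary with a JSON sidecar
#'
#' Stores samples as little-endian float32 (channel-major: all samples of
#' channel 1, then channel 2, ...) in `<path>.bin` and the metadata —
#' sampling rate, dimensions, stage and electrode grid — in `<path>.json`.
#'
#' @param rec A [voltage_recording()].
#' @param path Path stem (without extension).
#' @return `write_voltage_bin()` the path stem, invisibly;
#'   `read_voltage_bin()` a `voltage_recording`.
#' @export
write_voltage_bin <- function(rec, path) {
  stopifnot(inherits(rec, "voltage_recording"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  meta <- list(fs_hz = rec$fs, n_channels = nrow(rec$samples),
               n_samples = ncol(rec$samples), stage = rec$stage,
               dtype = "float32-le", order = "channel-major",
               electrode_rows = rec$electrodes$row,
               electrode_cols = rec$electrodes$col)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_voltage_bin
#' @export
read_voltage_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  samples <- matrix(v, nrow = meta$n_channels, byrow = TRUE)
  voltage_recording(samples, fs = meta$fs_hz,
                    electrodes = tibble(electrode = seq_len(meta$n_channels),
                                        row = meta$electrode_rows,
                                        col = meta$electrode_cols),
                    stage = meta$stage)
}

#' Read and write spike lists as CSV
#'
#' The interchange format is a two-column CSV with header `electrode,time_s`:
#' 0-based electrode index and spike time in seconds, written with 6 decimal
#' places. In-memory `spike_trains` use 1-based electrode indices; the
#' offset is applied on read/write.
#'
#' @param trains A `spike_trains` object.
#' @param path CSV path.
#' @param duration,n_electrodes Recording metadata required on read (a spike
#'   list alone does not determine them).
#' @return `write_spike_csv()` the path, invisibly; `read_spike_csv()` a
#'   `spike_trains` with provenance `"loaded"`.
#' @export
write_spike_csv <- function(trains, path) {
  stopifnot(inherits(trains, "spike_trains"))
  df <- data.frame(electrode = trains$electrode - 1L,
                   time_s = sprintf("%.6f", trains$time_s))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path, duration, n_electrodes) {
  df <- utils::read.csv(path)
  stopifnot(all(c("electrode", "time_s") %in% names(df)))
  new_spike_trains(tibble(electrode = df$electrode + 1L,
                          time_s = df$time_s),
                   duration = duration, n_electrodes = n_electrodes,
                   provenance = "loaded")
}
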