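#' Bin spike trains into fixed-width count vectors
#'
#' Non-overlapping bins of `width` seconds (default 50 ms, the resolution at
#' which multi-unit correlations are estimated). Bin `b` covers
#' `[b * width, (b + 1) * width)` — half-open, so a spike landing exactly on
#' an edge belongs to the later bin. A trailing partial bin is discarded.
#'
#' @param trains A `spike_trains` object.
#' @param width Bin width in seconds.
#' @return A `binned_spikes`: list with `counts` (electrodes x bins integer
#'   matrix), `width`, `duration` and `n_bins`.
#' @export
bin_spike_counts <- function(trains, width = 0.05) {
  stopifnot(inherits(trains, "spike_trains"), width > 0)
  n_bins <- floor(train_duration(trains) / width)
  n_e <- n_electrodes(trains)
  counts <- matrix(0L, n_e, n_bins)
  keep <- trains$time_s < n_bins * width
  if (any(keep)) {
    b <- floor(trains$time_s[keep] / width)  # 0-based bin
    idx <- b * n_e + trains$electrode[keep]  # combined (bin, electrode) index
    counts <- matrix(tabulate(idx, nbins = n_e * n_bins), n_e, n_bins)
  }
  structure(list(counts = counts, width = width,
                 duration = train_duration(trains), n_bins = n_bins),
            class = "binned_spikes")
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("<binned_spikes> %d electrodes x %d bins (%.0f-ms bins)\n",
              nrow(x$counts), x$n_bins, x$width * 1000))
  invisible(x)
}

fisher_z <- function(rho, clip = 1 - 1e-7) atanh(pmin(pmax(rho, -clip), clip))

#' Pairwise functional connectivity from binned spike counts
#'
#' Pearson correlation between the binned spike-count vectors of every
#' unordered electrode pair, Fisher z-transformed (`atanh`, with the
#' correlation clipped to `+-(1 - 1e-7)` so perfectly collinear pairs stay
#' finite). When a burst mask is supplied and `exclude_bursts = TRUE`,
#' correlations are computed over non-burst bins only: correlation between
#' spike trains is positively biased during epochs of high shared rate, so
#' population bursts would inflate every pairwise estimate.
#'
#' Pairs in which either electrode has zero variance over the used bins
#' carry no correlation information; they are marked invalid (`NA` in `z`,
#' `FALSE` in `valid`) and excluded from summaries rather than zero-filled.
#'
#' @param binned A [bin_spike_counts()] result.
#' @param burst_mask Optional [detect_population_bursts()] result.
#' @param exclude_bursts Drop burst bins before correlating.
#' @return An `fc_matrix`: list with `z` (symmetric matrix, `NA` diagonal and
#'   invalid entries), `valid` (logical matrix), `n_bins_used` and
#'   `burst_excluded`.
#' @export
pairwise_fc <- function(binned, burst_mask = NULL, exclude_bursts = TRUE) {
  stopifnot(inherits(binned, "binned_spikes"))
  use <- rep(TRUE, binned$n_bins)
  excluded <- FALSE
  if (!is.null(burst_mask) && exclude_bursts) {
    stopifnot(inherits(burst_mask, "burst_mask"),
              length(burst_mask$flags) == binned$n_bins)
    use <- !burst_mask$flags
    excluded <- TRUE
  }
  if (sum(use) < 2)
    abort("fewer than 2 usable bins remain after burst exclusion; the burst mask is over-aggressive")
  m <- binned$counts[, use, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  ok <- sds > 0
  rho <- suppressWarnings(stats::cor(t(m)))
  z <- fisher_z(rho)
  valid <- outer(ok, ok, `&`)
  diag(valid) <- FALSE
  z[!valid] <- NA_real_
  diag(z) <- NA_real_
  structure(list(z = z, valid = valid, n_bins_used = sum(use),
                 burst_excluded = excluded),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  n <- nrow(x$z)
  nv <- sum(x$valid[upper.tri(x$valid)])
  cat(sprintf("<fc_matrix> %d electrodes, %d/%d valid pairs, %d bins used%s\n",
              n, nv, n * (n - 1) / 2, x$n_bins_used,
              if (x$burst_excluded) " (burst bins excluded)" else ""))
  invisible(x)
}

#' @describeIn pairwise_fc Long-format tibble of unordered pairs
#'   (`i < j`) with columns `i`, `j`, `z`, `valid`.
#' @param x An `fc_matrix`.
#' @param ... Unused.
#' @export
tidy.fc_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$z), arr.ind = TRUE)
  tibble(i = ut[, 1], j = ut[, 2], z = x$z[ut], valid = x$valid[ut]) %>%
    arrange(.data$i, .data$j)
}

#' @describeIn pairwise_fc One-row summary: mean/SD of valid-pair z, counts.
#' @export
glance.fc_matrix <- function(x, ...) {
  zz <- x$z[upper.tri(x$z)][x$valid[upper.tri(x$valid)]]
  tibble(mean_z = mean(zz), sd_z = stats::sd(zz), n_valid_pairs = length(zz),
         n_bins_used = x$n_bins_used, burst_excluded = x$burst_excluded)
}

#' Effect of including burst bins on connectivity estimates
#'
#' Computes the mean valid-pair Fisher z twice from the same binned matrix —
#' once over all bins and once excluding burst bins — quantifying how much
#' shared-rate epochs inflate the correlation-based estimate. With an empty
#' mask the two values coincide by construction.
#'
#' @param binned A [bin_spike_counts()] result.
#' @param burst_mask A [detect_population_bursts()] result.
#' @return A one-row tibble with `z_with`, `z_without`, `n_burst_bins`.
#' @export
burst_bias_check <- function(binned, burst_mask) {
  stopifnot(inherits(burst_mask, "burst_mask"))
  z_with <- glance(pairwise_fc(binned, burst_mask,
                               exclude_bursts = FALSE))$mean_z
  z_without <- glance(pairwise_fc(binned, burst_mask,
                                  exclude_bursts = TRUE))$mean_z
  tibble(z_with = z_with, z_without = z_without,
         n_burst_bins = sum(burst_mask$flags))
}

#' Threshold a connectivity matrix into a network graph
#'
#' Keeps valid unordered pairs with Fisher z above `z_min` (default 0.80,
#' the conventional cut for "strong" connections in this pipeline) as edges
#' and tallies per-node degree.
#'
#' @param fc An `fc_matrix`.
#' @param z_min Edge threshold on Fisher z.
#' @return A `network_graph`: list with `edges` (tibble `i`, `j`, `z`;
#'   `i < j`) and `degrees` (tibble `electrode`, `degree`).
#' @export
threshold_network <- function(fc, z_min = 0.80) {
  stopifnot(inherits(fc, "fc_matrix"))
  long <- tidy(fc)
  edges <- dplyr::filter(long, .data$valid, .data$z > z_min) %>%
    select("i", "j", "z")
  n <- nrow(fc$z)
  deg <- tabulate(c(edges$i, edges$j), nbins = n)
  structure(list(edges = edges,
                 degrees = tibble(electrode = seq_len(n), degree = deg),
                 z_min = z_min),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d edges (z > %.2f) over %d nodes\n",
              nrow(x$edges), x$z_min, nrow(x$degrees)))
  invisible(x)
}

#' @export
tidy.network_graph <- function(x, ...) x$edges

#' Write a connectivity matrix as CSV
#'
#' `write_fc_long_csv()` writes the unordered-pair long format
#' (`i,j,z,valid`); `write_fc_matrix_csv()` the square z matrix.
#'
#' @param fc An `fc_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fc_long_csv <- function(fc, path) {
  utils::write.csv(as.data.frame(tidy(fc)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_fc_long_csv
#' @export
write_fc_matrix_csv <- function(fc, path) {
  utils::write.csv(as.data.frame(fc$z), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
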