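# Shared test utilities: rank-based AUROC, least-squares tone amplitude,
# and a direct binned-count constructor for connectivity tests.

rank_auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Amplitude of a sinusoid at frequency f in x, by least squares over the
# central portion (edges dropped to avoid filter transients).
tone_amplitude <- function(x, f, fs, trim = 0.2) {
  n <- length(x)
  keep <- seq(floor(trim * n) + 1, ceiling((1 - trim) * n))
  t <- (keep - 1) / fs
  X <- cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::.lm.fit(X, x[keep])$coefficients
  sqrt(cf[2]^2 + cf[3]^2)
}

# Build a binned_spikes object directly from a counts matrix.
make_binned <- function(counts, width = 0.05) {
  structure(list(counts = counts, width = width,
                 duration = ncol(counts) * width, n_bins = ncol(counts)),
            class = "binned_spikes")
}

# Build a spike_trains object from a data frame of electrode/time pairs.
make_trains <- function(electrode, time_s, duration, n_electrodes) {
  seiznet:::new_spike_trains(
    tibble::tibble(electrode = electrode, time_s = time_s),
    duration = duration, n_electrodes = n_electrodes,
    provenance = "loaded")
}

# One simulated treatment replicate reduced to per-well, per-day summaries
# (normalized MFR, strong edges, trajectory distance); used by treatment
# direction tests.
course_summaries <- function(seed, n_electrodes = 64, duration = 300,
                             base_rate = 2, n_pairs = 16, weight = 0.2,
                             rate_multipliers = c(1, 1.9, 2.5),
                             coupling_boost = 3, n_wells = 9,
                             z_min = 0.80) {
  set.seed(seed)
  W <- paired_coupling(n_electrodes, n_pairs, weight)
  well <- well_config(n_electrodes, duration, base_rate, W)
  des <- treatment_design(rate_multipliers = rate_multipliers,
                          coupling_boost = coupling_boost,
                          n_treated_wells = n_wells,
                          n_control_wells = n_wells)
  course <- simulate_treatment_course(well, des, seed = seed)
  course$binned <- lapply(course$trains, bin_spike_counts)
  course$mask <- lapply(course$binned, detect_population_bursts)
  course$fc <- mapply(pairwise_fc, course$binned, course$mask,
                      SIMPLIFY = FALSE)
  course$mfr <- vapply(course$trains, function(tr)
    mean_firing_rate(tr)$well_mean_hz, numeric(1))
  course$edges <- vapply(course$fc, function(f)
    nrow(threshold_network(f, z_min)$edges), integer(1))
  last <- max(course$day)
  per_well <- lapply(split(seq_len(nrow(course)), course$well), function(i) {
    sub <- course[i, ]
    traj <- embed_well(sub$fc[order(sub$day)])
    data.frame(well = sub$well[1], group = sub$group[1],
               norm_mfr = sub$mfr[sub$day == last] / sub$mfr[sub$day == 0],
               edges = sub$edges[sub$day == last],
               dist = traj$distances[length(traj$distances)])
  })
  do.call(rbind, per_well)
}
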