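test_that("zero-rate configurations produce empty trains", {
  cfg <- well_config(8, 10, base_rate = 0, burst_rate = 0, seed = 1)
  st <- simulate_spike_trains(cfg)
  expect_equal(nrow(st), 0L)
  expect_equal(train_duration(st), 10)
  expect_equal(n_electrodes(st), 8L)
})

test_that("uncoupled constant-rate wells are Poisson-like at the nominal rate", {
  cfg <- well_config(64, 300, base_rate = 2, burst_rate = 0, seed = 20)
  st <- simulate_spike_trains(cfg)
  counts <- tabulate(st$electrode, nbins = 64)
  # Bernoulli(300000, 0.002): mean 600, sd ~ sqrt(600); 4-sigma band
  in_band <- abs(counts - 600) <= 4 * sqrt(600)
  expect_gte(sum(in_band), 62)
  expect_true(all(st$time_s >= 0 & st$time_s < 300))
  expect_false(is.unsorted(st$time_s[st$electrode == 1]))
})

test_that("identical config and seed give bit-identical trains", {
  cfg <- well_config(16, 30, base_rate = 3, seed = 77)
  a <- simulate_spike_trains(cfg)
  b <- simulate_spike_trains(cfg)
  expect_identical(a$electrode, b$electrode)
  expect_identical(a$time_s, b$time_s)
  cfg2 <- cfg; cfg2$seed <- 78
  c <- simulate_spike_trains(cfg2)
  expect_false(identical(a$time_s, c$time_s))
})

test_that("expected counts scale linearly with base rate", {
  n_tot <- function(rate, seed) {
    nrow(simulate_spike_trains(
      well_config(32, 120, rate, burst_rate = 0, seed = seed)))
  }
  counts1 <- sapply(1:5, function(s) n_tot(2, s))
  counts2 <- sapply(1:5, function(s) n_tot(4, s + 100))
  ratio <- mean(counts2) / mean(counts1)
  # expectation 2; sampling error tiny at ~9600 spikes per draw
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("config invariants are enforced", {
  expect_error(well_config(4, 10, coupling = matrix(1, 3, 3)),
               "n_electrodes")
  W <- matrix(0.1, 4, 4)
  expect_error(well_config(4, 10, coupling = W), "diagonal")
  diag(W) <- 0
  expect_silent(well_config(4, 10, coupling = W))
  expect_error(well_config(4, 10, burst_gain = 0.5), "burst_gain")
  expect_error(well_config(4, 10, base_rate = -1), "rates")
  expect_error(treatment_design(n_days = 1), "n_days")
  expect_error(treatment_design(rate_multipliers = c(2, 1.9, 2.5)),
               "Day-0")
})

test_that("a directed coupled pair stands out from the uncoupled FC background", {
  hits <- sapply(1:20, function(s) {
    W <- matrix(0, 16, 16)
    W[1, 2] <- 0.3
    st <- simulate_spike_trains(
      well_config(16, 120, 2, W, burst_rate = 0, seed = 200 + s))
    z <- suppressWarnings(pairwise_fc(bin_spike_counts(st)))$z
    others <- z[upper.tri(z)]
    others <- others[-1]  # drop the (1,2) entry itself
    z[1, 2] > stats::quantile(others, 0.95, na.rm = TRUE)
  })
  expect_gte(sum(hits), 19)
})

test_that("treatment course structure, labeling and null design behave", {
  W <- paired_coupling(8, 2, 0.2)
  well <- well_config(8, 20, 2, W)
  des <- treatment_design(n_treated_wells = 2, n_control_wells = 2)
  course <- simulate_treatment_course(well, des, seed = 5)
  expect_equal(nrow(course), 12)  # 4 wells x 3 days
  expect_setequal(unique(course$group), c("treated", "control"))
  expect_equal(sort(unique(course$day)), 0:2)
  # identical seed reproduces; adding wells must not perturb existing ones
  course2 <- simulate_treatment_course(well, des, seed = 5)
  expect_identical(course$trains[[1]]$time_s, course2$trains[[1]]$time_s)
  des_more <- treatment_design(n_treated_wells = 3, n_control_wells = 2)
  course3 <- simulate_treatment_course(well, des_more, seed = 5)
  expect_identical(course$trains[[1]]$time_s, course3$trains[[1]]$time_s)
})

test_that("null treatment design is distribution-identical across groups", {
  des <- treatment_design(rate_multipliers = c(1, 1, 1), coupling_boost = 1,
                          n_treated_wells = 3, n_control_wells = 3)
  well <- well_config(16, 60, 2, burst_rate = 0)
  diffs <- sapply(1:20, function(r) {
    course <- simulate_treatment_course(well, des, seed = 1000 + r)
    mfr <- vapply(course$trains, function(tr)
      mean_firing_rate(tr)$well_mean_hz, numeric(1))
    mean(mfr[course$group == "treated"]) -
      mean(mfr[course$group == "control"])
  })
  expect_gt(stats::t.test(diffs)$p.value, 0.05)
})

test_that("day-2 rate multiplier is recovered in normalized MFR", {
  des <- treatment_design(n_treated_wells = 4, n_control_wells = 2)
  well <- well_config(16, 120, 2, burst_rate = 0)  # no coupling
  ratios <- sapply(1:20, function(r) {
    course <- simulate_treatment_course(well, des, seed = 2000 + r)
    tr <- course[course$group == "treated", ]
    mfr <- vapply(tr$trains, function(x)
      mean_firing_rate(x)$well_mean_hz, numeric(1))
    mean(mfr[tr$day == 2]) / mean(mfr[tr$day == 0])
  })
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2.5), 4 * se + 0.05)
})

test_that("boosted edges rank in the top decile of day-2 connectivity", {
  hits <- sapply(1:20, function(r) {
    set.seed(3000 + r)
    W <- random_coupling(32, 0.05, 0.1)
    tp <- attr(W, "true_pairs")
    well <- well_config(32, 150, 2, W, burst_rate = 0)
    des <- treatment_design(n_treated_wells = 1, n_control_wells = 1,
                            coupling_boost = 3)
    course <- simulate_treatment_course(well, des, seed = 3000 + r)
    day2 <- course[course$group == "treated" & course$day == 2, ]
    fc <- suppressWarnings(pairwise_fc(bin_spike_counts(day2$trains[[1]])))
    long <- tidy(fc)
    truth <- paste(long$i, long$j) %in% paste(tp$i, tp$j)
    cut <- stats::quantile(long$z[long$valid], 0.9, na.rm = TRUE)
    mean(long$z[truth] > cut, na.rm = TRUE) > 0.5
  })
  expect_gte(sum(hits), 16)
})

test_that("synthetic voltage has the declared noise floor and injection site", {
  st <- make_trains(integer(0), numeric(0), duration = 1, n_electrodes = 2)
  tmpl <- spike_template(amp_uV = 80, noise_sd = 10)
  rec <- simulate_voltage(st, tmpl, fs = 12500, seed = 9)
  expect_equal(dim(rec$samples), c(2, 12500))
  expect_lt(abs(sd(rec$samples[1, ]) - 10) / 10, 0.05)

  one <- make_trains(1L, 1.0, duration = 2, n_electrodes = 1)
  tiny <- spike_template(amp_uV = 80, noise_sd = 1e-9)
  recs <- simulate_voltage(one, tiny, fs = 12500, seed = 10)
  # template peak lands exactly on sample round(1.0 * fs) (0-based)
  expect_equal(which.max(abs(recs$samples[1, ])) - 1L, 12500L)
})

test_that("injected line noise shows a 60 Hz spectral peak", {
  st <- make_trains(integer(0), numeric(0), duration = 2, n_electrodes = 1)
  tmpl <- spike_template(amp_uV = 80, noise_sd = 1, line_amp = 50)
  rec <- simulate_voltage(st, tmpl, fs = 12500, seed = 11)
  x <- rec$samples[1, ]
  spec <- Mod(fft(x))[1:(length(x) / 2)]
  freqs <- (seq_along(spec) - 1) / 2
  expect_equal(freqs[which.max(spec[-1]) + 1], 60)
})

test_that("phase-coupled pairs have the prescribed synchrony", {
  p <- simulate_phase_coupled_pair(5000, 1000, kappa = Inf, seed = 1)
  expect_equal(plv(p$x, p$y), 1, tolerance = 1e-12)
  expect_equal(p$expected_plv, 1)
  # kappa = 0: PLV decays with the effective number of independent phase
  # draws (n_cycles / corr_cycles); Rayleigh mean is sqrt(pi)/2 / sqrt(n)
  v0 <- sapply(1:10, function(s)
    with(simulate_phase_coupled_pair(10000, 1000, kappa = 0, seed = s),
         plv(x, y)))
  n_eff <- (10000 / 1000 * 80) / 8
  expect_lt(abs(mean(v0) - sqrt(pi) / 2 / sqrt(n_eff)),
            4 * sd(v0) / sqrt(10) + 0.02)
  expect_error(simulate_phase_coupled_pair(1000, 1000, kappa = -1), "kappa")
})

test_that("band-limited noise is confined to its band", {
  x <- simulate_bandlimited_noise(8192, 1000, c(70, 90), seed = 3)
  spec <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * 1000 / length(x)
  f <- pmin(f, 1000 - f)
  in_band <- f >= 70 & f <= 90
  expect_gt(sum(spec[in_band]) / sum(spec), 0.999)
  expect_equal(sd(x), 1, tolerance = 1e-9)
})

test_that("iceeg cohort generator produces a labeled pair table", {
  co <- simulate_iceeg_cohort(n_patients = 2, n_pairs_per_class = 2,
                              n_samples = 500, fs = 500, band = c(70, 90),
                              seed = 4)
  expect_equal(nrow(co), 8)
  expect_setequal(unique(co$class), c("SOZ-SP", "SOZ-control"))
  expect_length(co$x[[1]], 500)
})
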