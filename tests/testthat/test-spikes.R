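test_that("detection refuses raw input and finds nothing in silence", {
  raw <- voltage_recording(matrix(rnorm(1000), 1), 2500, stage = "raw")
  expect_error(detect_spikes(raw), "conditioned")
  silent <- voltage_recording(matrix(0, 2, 2500), 2500, stage = "zscored")
  expect_equal(nrow(detect_spikes(silent)), 0L)
})

test_that("false positives on pure noise stay below 0.5 Hz per channel", {
  fs <- 12500
  set.seed(31)
  rec <- voltage_recording(matrix(rnorm(2 * 60 * fs, sd = 10), nrow = 2), fs)
  cond <- condition_recording(rec, zero_phase = TRUE)
  det <- detect_spikes(cond)
  # score away from the band-pass settle transient at the record edges
  interior <- det$time_s > 2 & det$time_s < 58
  expect_lt(sum(interior) / (2 * 56), 0.5)
})

test_that("injected events are recovered with high fidelity and sub-ms timing", {
  rt <- spike_detection_roundtrip(n_electrodes = 8, duration = 20,
                                  base_rate = 1, seed = 5)
  expect_gte(rt$recall, 0.95)
  expect_gte(rt$precision, 0.95)
  expect_lte(rt$max_abs_dt_s, 0.001)
})

test_that("detection is invariant to positive rescaling of the trace", {
  fs <- 2500
  set.seed(32)
  x <- rnorm(fs * 4)
  x[c(2000, 5000, 8000)] <- 12
  rec1 <- voltage_recording(matrix(x, 1), fs, stage = "filtered")
  rec2 <- voltage_recording(matrix(37.5 * x, 1), fs, stage = "filtered")
  expect_identical(detect_spikes(rec1)$time_s, detect_spikes(rec2)$time_s)
})

test_that("events within the dead time merge to the larger peak", {
  fs <- 1000
  set.seed(44)
  x <- rnorm(fs, sd = 0.1)
  x[500] <- 5; x[501] <- -8  # 1 ms apart, inside the 2-ms dead time
  rec <- voltage_recording(matrix(x, 1), fs, stage = "zscored")
  det <- detect_spikes(rec, k = 5.5, dead_time = 0.002)
  expect_equal(nrow(det), 1L)
  expect_equal(unname(det$time_s), 500 / fs)  # the larger |peak| wins
})

test_that("mean firing rate follows its definition", {
  tr <- make_trains(rep(1L, 10), seq(0.1, 4.9, length.out = 10),
                    duration = 5, n_electrodes = 2)
  m <- mean_firing_rate(tr)
  expect_equal(m$per_electrode$rate_hz, c(2, 0))
  expect_equal(m$well_mean_hz, 1)
  empty <- make_trains(integer(0), numeric(0), 5, 4)
  expect_equal(mean_firing_rate(empty)$well_mean_hz, 0)
})

test_that("simulated well MFR lands inside the Poisson sampling band", {
  st <- simulate_spike_trains(well_config(64, 300, 2, burst_rate = 0,
                                          seed = 33))
  m <- mean_firing_rate(st)
  se <- sqrt(2 / (64 * 300))  # SE of the well mean under Poisson counts
  expect_lt(abs(m$well_mean_hz - 2), 4 * se)
})

test_that("MFR of concatenated recordings averages the parts", {
  t1 <- make_trains(c(1L, 1L, 2L), c(0.5, 1.5, 2.0), 4, 2)
  t2 <- make_trains(c(1L, 2L, 2L), c(1.0, 2.5, 3.0), 4, 2)
  cat12 <- make_trains(c(t1$electrode, t2$electrode),
                       c(t1$time_s, t2$time_s + 4), 8, 2)
  expect_equal(mean_firing_rate(cat12)$well_mean_hz,
               (mean_firing_rate(t1)$well_mean_hz +
                  mean_firing_rate(t2)$well_mean_hz) / 2)
})

test_that("normalization to baseline is a plain ratio with a guarded zero", {
  a <- mean_firing_rate(make_trains(rep(1L, 8), seq(0.1, 3.9, length.out = 8),
                                    4, 2))
  expect_equal(normalize_mfr(a, a)$ratio, 1)
  b <- mean_firing_rate(make_trains(rep(1L, 16),
                                    seq(0.05, 3.95, length.out = 16), 4, 2))
  expect_equal(normalize_mfr(b, a)$ratio, 2)
  z <- mean_firing_rate(make_trains(integer(0), numeric(0), 4, 2))
  expect_warning(res <- normalize_mfr(a, z), "undefined")
  expect_false(res$defined)
  expect_true(is.na(res$ratio))
})

test_that("treated synthetic course recovers the 2.5x ratio through the op", {
  des <- treatment_design(n_treated_wells = 3, n_control_wells = 2)
  well <- well_config(16, 120, 2, burst_rate = 0)
  ratios <- sapply(1:10, function(r) {
    course <- simulate_treatment_course(well, des, seed = 4000 + r)
    tr <- course[course$group == "treated", ]
    base <- mean_firing_rate(tr$trains[[which(tr$day == 0)[1]]])
    day2 <- mean_firing_rate(tr$trains[[which(tr$day == 2)[1]]])
    normalize_mfr(day2, base)$ratio
  })
  expect_lt(abs(mean(ratios) - 2.5), 4 * sd(ratios) / sqrt(10) + 0.05)
})

test_that("population-burst detection is calibrated on nulls and finds volleys", {
  # homogeneous independent trains: almost no burst bins
  frac <- sapply(1:20, function(s) {
    st <- simulate_spike_trains(well_config(16, 60, 3, burst_rate = 0,
                                            seed = 500 + s))
    m <- detect_population_bursts(bin_spike_counts(st))
    mean(m$flags)
  })
  expect_lt(mean(frac), 0.01)

  # injected synchronous volley on half the electrodes for 200 ms
  st <- simulate_spike_trains(well_config(16, 60, 2, burst_rate = 0,
                                          seed = 600))
  volley <- tidyr::expand_grid(electrode = 1:8,
                               time_s = seq(30.0, 30.19, by = 0.01))
  aug <- make_trains(c(st$electrode, volley$electrode),
                     c(st$time_s, volley$time_s), 60, 16)
  mask <- detect_population_bursts(bin_spike_counts(aug))
  expect_gt(nrow(mask$intervals), 0)
  expect_true(any(mask$intervals$start_s < 30.2 &
                    mask$intervals$end_s > 30.0))

  # all-zero well: no bursts
  zero <- make_trains(integer(0), numeric(0), 10, 8)
  expect_equal(sum(detect_population_bursts(bin_spike_counts(zero))$flags), 0)
})

test_that("raising the burst threshold never adds burst bins", {
  st <- simulate_spike_trains(well_config(16, 60, 3, seed = 42))
  b <- bin_spike_counts(st)
  m2 <- detect_population_bursts(b, rate_sd = 2)
  m3 <- detect_population_bursts(b, rate_sd = 3)
  m5 <- detect_population_bursts(b, rate_sd = 5)
  expect_true(all(m3$flags <= m2$flags))
  expect_true(all(m5$flags <= m3$flags))
})

test_that("spike and burst CSV round trips preserve content", {
  st <- simulate_spike_trains(well_config(4, 10, 3, seed = 7))
  path <- file.path(tempdir(), "spikes.csv")
  write_spike_csv(st, path)
  back <- read_spike_csv(path, duration = 10, n_electrodes = 4)
  expect_equal(back$electrode, st$electrode)
  expect_equal(back$time_s, st$time_s, tolerance = 1e-6)
  expect_equal(attr(back, "provenance"), "loaded")

  mask <- detect_population_bursts(bin_spike_counts(st))
  bpath <- file.path(tempdir(), "bursts.csv")
  write_burst_csv(mask, bpath)
  got <- utils::read.csv(bpath)
  expect_equal(names(got), c("start_s", "end_s"))
})
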