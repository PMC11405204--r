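test_that("binning follows the half-open 50-ms convention", {
  tr <- make_trains(c(1L, 1L, 1L), c(0.01, 0.04, 0.06), 0.1, 2)
  b <- bin_spike_counts(tr)
  expect_equal(b$counts[1, ], c(2, 1))
  expect_equal(b$counts[2, ], c(0, 0))
  # a spike exactly on the edge belongs to the later bin
  edge <- bin_spike_counts(make_trains(1L, 0.05, 0.1, 1))
  expect_equal(edge$counts[1, ], c(0, 1))
  # trailing partial bin discarded
  part <- bin_spike_counts(make_trains(1L, 0.12, 0.13, 1))
  expect_equal(part$n_bins, 2)
  expect_equal(sum(part$counts), 0)
})

test_that("Fisher z handles perfect and known correlations", {
  x <- c(10L, 20L, 30L, 40L, 50L)
  fc_same <- pairwise_fc(make_binned(rbind(x, x)))
  expect_equal(fc_same$z[1, 2], atanh(1 - 1e-7))
  expect_equal(fc_same$z[1, 2], 0.5 * log((2 - 1e-7) / 1e-7),
               tolerance = 1e-9)
  # y built as 0.8 x + orthogonal residual of equal scale: cor exactly 0.8
  y <- c(14L, 4L, 24L, 44L, 34L)
  expect_equal(cor(x, y), 0.8)
  fc <- pairwise_fc(make_binned(rbind(x, y)))
  expect_equal(fc$z[1, 2], 0.5 * log(9), tolerance = 1e-12)
  expect_equal(fc$z[1, 2], fc$z[2, 1])
})

test_that("independent trains give near-zero mean z at the Fisher scale", {
  st <- simulate_spike_trains(well_config(16, 120, 3, burst_rate = 0,
                                          seed = 50))
  fc <- pairwise_fc(bin_spike_counts(st))
  expect_lt(abs(glance(fc)$mean_z), 2 / sqrt(fc$n_bins_used))
})

test_that("zero-variance electrodes are invalidated, not zero-filled", {
  counts <- rbind(c(1L, 2L, 3L, 4L), c(0L, 0L, 0L, 0L), c(4L, 3L, 2L, 1L))
  fc <- pairwise_fc(make_binned(counts))
  expect_false(fc$valid[1, 2])
  expect_true(is.na(fc$z[1, 2]))
  expect_true(fc$valid[1, 3])
  expect_equal(glance(fc)$n_valid_pairs, 1)
  long <- tidy(fc)
  expect_equal(nrow(long), 3)
  expect_equal(sum(long$valid), 1)
})

test_that("burst exclusion uses only non-burst bins and errors when starved", {
  counts <- rbind(c(1L, 2L, 1L, 9L, 3L), c(2L, 1L, 2L, 9L, 1L))
  flags <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  mask <- structure(list(intervals = tibble::tibble(start_s = 0.15,
                                                    end_s = 0.2),
                         flags = flags, params = list()),
                    class = "burst_mask")
  b <- make_binned(counts)
  fc_ex <- pairwise_fc(b, mask)
  manual <- atanh(cor(counts[1, !flags], counts[2, !flags]))
  expect_equal(fc_ex$z[1, 2], manual)
  expect_equal(fc_ex$n_bins_used, 4)
  starve <- structure(list(intervals = tibble::tibble(),
                           flags = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                           params = list()), class = "burst_mask")
  expect_error(pairwise_fc(b, starve), "burst mask")
})

test_that("an empty burst mask makes inclusion and exclusion coincide", {
  st <- simulate_spike_trains(well_config(8, 30, 3, burst_rate = 0,
                                          seed = 51))
  b <- bin_spike_counts(st)
  mask <- detect_population_bursts(b)
  if (sum(mask$flags) == 0) {
    res <- burst_bias_check(b, mask)
    expect_equal(res$z_with, res$z_without)
  }
  # constructed empty mask gives exact equality regardless
  empty <- structure(list(intervals = tibble::tibble(),
                          flags = rep(FALSE, b$n_bins), params = list()),
                     class = "burst_mask")
  res2 <- burst_bias_check(b, empty)
  expect_identical(res2$z_with, res2$z_without)
})

test_that("shared-rate bursts inflate correlation estimates directionally", {
  res <- sapply(1:5, function(s) {
    st <- simulate_spike_trains(well_config(32, 120, 2, burst_rate = 6,
                                            burst_duration = 0.3,
                                            burst_gain = 5, seed = 700 + s))
    b <- bin_spike_counts(st)
    m <- detect_population_bursts(b)
    bb <- burst_bias_check(b, m)
    bb$z_with > bb$z_without
  })
  expect_gte(sum(res), 4)
})

test_that("thresholding yields consistent edges and degrees", {
  z <- matrix(0.5, 4, 4); diag(z) <- NA
  valid <- matrix(TRUE, 4, 4); diag(valid) <- FALSE
  fc <- structure(list(z = z, valid = valid, n_bins_used = 100,
                       burst_excluded = FALSE), class = "fc_matrix")
  net <- threshold_network(fc)
  expect_equal(nrow(net$edges), 0)
  expect_true(all(net$degrees$degree == 0))
  z[1, 3] <- z[3, 1] <- 0.9
  fc$z <- z
  net2 <- threshold_network(fc)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$i, 1)
  expect_equal(net2$edges$j, 3)
  expect_equal(net2$degrees$degree, c(1, 0, 1, 0))
})

test_that("electrode permutation permutes the FC matrix consistently", {
  st <- simulate_spike_trains(well_config(8, 60, 3, burst_rate = 0,
                                          seed = 52))
  b <- bin_spike_counts(st)
  fc <- pairwise_fc(b)
  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 5L, 7L)
  bp <- make_binned(b$counts[perm, ], b$width)
  fcp <- pairwise_fc(bp)
  expect_equal(fcp$z, fc$z[perm, perm], tolerance = 1e-12)
})

test_that("the Fisher transform preserves pair ranking", {
  rho <- runif(50, -0.95, 0.95)
  expect_equal(order(atanh(rho)), order(rho))
  expect_true(all(diff(atanh(sort(rho))) > 0))
})

test_that("the rank AUROC used for edge recovery matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(54)
  for (r in 1:5) {
    truth <- runif(200) < 0.2
    score <- rnorm(200) + truth
    ours <- rank_auroc(score, truth)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("FC matrices write to long and square CSV", {
  st <- simulate_spike_trains(well_config(4, 20, 3, seed = 53))
  fc <- pairwise_fc(bin_spike_counts(st))
  p1 <- file.path(tempdir(), "fc_long.csv")
  p2 <- file.path(tempdir(), "fc_sq.csv")
  write_fc_long_csv(fc, p1)
  write_fc_matrix_csv(fc, p2)
  long <- utils::read.csv(p1)
  expect_equal(names(long), c("i", "j", "z", "valid"))
  expect_equal(nrow(long), 6)
  sq <- utils::read.csv(p2)
  expect_equal(dim(sq), c(4, 4))
})
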