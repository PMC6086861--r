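test_that("volume discard removes leading frames of each run, preserving order", {
  sig <- matrix(seq_len(20), nrow = 10, ncol = 2)
  ts <- fc_timeseries(sig, motion = matrix(0, 10, 6))
  out <- discard_initial_volumes(ts, 5)
  expect_equal(out$signal[, 1], 6:10)
  expect_equal(nrow(out$motion), 5L)

  ts246 <- fc_timeseries(matrix(rnorm(246 * 3), 246, 3))
  expect_equal(nrow(discard_initial_volumes(ts246, 5, n_runs = 2)$signal), 236L)
  expect_identical(discard_initial_volumes(ts, 0), ts)
  expect_error(discard_initial_volumes(ts, 10), "discard")
})

test_that("detrending removes quadratic trends and the band-pass has the right response", {
  n <- 160; tt <- seq_len(n)
  quad <- matrix(0.02 * tt^2 - tt + 3, n, 1)
  f <- bandpass_detrend(fc_timeseries(quad, tr = 2))
  expect_lt(sqrt(mean(f$signal^2)), 1e-6 * sqrt(mean(quad^2)))

  inband <- sin(2 * pi * 0.05 * tt * 2)     # 0.05 Hz at TR = 2 s
  stopband <- sin(2 * pi * 0.2 * tt * 2)    # 0.2 Hz
  sig <- cbind(inband, stopband)
  f2 <- bandpass_detrend(fc_timeseries(sig, tr = 2))
  expect_gt(sd(f2$signal[, 1]) / sd(inband), 0.9)
  expect_lt(sd(f2$signal[, 2]) / sd(stopband), 0.1)

  f3 <- bandpass_detrend(fc_timeseries(sig, tr = 2), method = "butterworth")
  expect_gt(sd(f3$signal[, 1]) / sd(inband), 0.9)
  expect_lt(sd(f3$signal[, 2]) / sd(stopband), 0.1)

  expect_error(bandpass_detrend(fc_timeseries(sig, tr = 2), 0.009, 0.3),
               "Nyquist|band")
})

test_that("framewise displacement follows its defining arithmetic", {
  m <- matrix(0, 6, 6)
  expect_equal(compute_fd(m), rep(0, 6))

  m[4:6, 1] <- 0.2      # 0.2 mm translation step at frame 4
  m[4:6, 4] <- 0.004    # 0.004 rad rotation step at frame 4
  fd <- compute_fd(m)
  expect_equal(fd[4], 0.2 + 50 * 0.004, tolerance = 1e-12)
  expect_equal(fd[c(1:3, 5:6)], rep(0, 5))

  m2 <- matrix(0, 4, 6); m2[3:4, 2] <- 0.85
  expect_true(any(compute_fd(m2) > 0.8))

  mdeg <- matrix(0, 3, 6); mdeg[2:3, 5] <- 0.004 * 180 / pi
  expect_equal(compute_fd(mdeg, rotations = "degrees")[2], 0.2,
               tolerance = 1e-12)
})

test_that("DVARS is the grand-mean-scaled RMS frame difference", {
  const <- matrix(100, 10, 5)
  expect_equal(compute_dvars(const), rep(0, 10))

  jump <- const; jump[6:10, ] <- 101   # uniform 1% jump at frame 6
  expect_equal(compute_dvars(jump, divisor = 100)[6], 0.01, tolerance = 1e-12)
  expect_equal(compute_dvars(jump)[6], 0.01, tolerance = 0.01)
  expect_true(all(compute_dvars(jump)[-6] == 0))

  big <- const; big[6:10, ] <- 106     # 6% jump crosses the 0.05 threshold
  expect_gt(compute_dvars(big)[6], 0.05)

  expect_error(compute_dvars(const - 100), "positive")
})

test_that("FD and DVARS are invariant to ROI reordering", {
  set.seed(4)
  sig <- 1000 + matrix(rnorm(50 * 8, sd = 10), 50, 8)
  perm <- sample(8)
  expect_equal(compute_dvars(sig), compute_dvars(sig[, perm]))
  m <- matrix(cumsum(rnorm(50 * 6, sd = 0.02)), 50, 6)
  expect_equal(compute_fd(m), compute_fd(m))  # trivially stable
})

test_that("scrubbing censors flag-union violations and is idempotent", {
  set.seed(8)
  sig <- 1000 + matrix(rnorm(10 * 6, sd = 1), 10, 6)
  sig[4, ] <- sig[4, ] + 200           # DVARS violation at frame 4 (and 5)
  motion <- matrix(0, 10, 6)
  motion[7:10, 1] <- 1.0               # FD violation at frame 7
  ts <- fc_timeseries(sig, motion = motion)
  qc <- compute_qc(ts)
  expect_false(all(qc$keep))
  res <- scrub(ts, qc, min_frames = 0L)
  expect_equal(res$qc$n_kept, nrow(res$ts$signal))
  expect_equal(sum(!qc$keep) + res$qc$n_kept, 10L)

  # re-scrubbing the scrubbed output removes nothing
  res2 <- scrub(res$ts, res$qc, min_frames = 0L)
  expect_equal(res2$qc$n_kept, res$qc$n_kept)
  expect_identical(res2$ts$signal, res$ts$signal)

  # clean data: everything kept
  clean <- fc_timeseries(1000 + matrix(rnorm(10 * 6), 10, 6),
                         motion = matrix(0, 10, 6))
  expect_equal(scrub(clean, min_frames = 0L)$qc$n_kept, 10L)
})

test_that("sessions below the frame minimum are flagged, not hard errors", {
  sig <- 1000 + matrix(rnorm(20 * 4), 20, 4)
  motion <- matrix(0, 20, 6)
  motion[seq(2, 20, by = 2), 1] <- seq(1, 10)  # big FD on every other frame
  ts <- fc_timeseries(sig, motion = motion)
  expect_warning(res <- scrub(ts, min_frames = 15L),
                 class = "rsfcnet_low_frames")
  expect_true(res$qc$exclude)
})

test_that("planted spikes are exactly the censored frames across a cohort", {
  cfg <- synthetic_config(n_per_group = c(I = 3L, NI = 2L), n_frames = 200L,
                          roi_count = 16L, motion_spike_rate = 0.1, seed = 31L)
  co <- simulate_cohort(cfg)
  for (key in names(co$sessions)) {
    qc <- compute_qc(co$sessions[[key]])
    expect_identical(which(!qc$keep),
                     as.integer(co$ground_truth$spike_frames[[key]]))
    res <- scrub(co$sessions[[key]], qc, min_frames = 0L)
    expect_equal(res$qc$n_kept,
                 200L - length(co$ground_truth$spike_frames[[key]]))
  }
})

test_that("interpolation over censored frames leaves surviving frames untouched", {
  set.seed(2)
  sig <- 1000 + matrix(rnorm(30 * 4, sd = 5), 30, 4)
  ts <- fc_timeseries(sig)
  bad <- c(7L, 15L, 16L)
  out <- interpolate_censored(ts, bad)
  expect_equal(out$signal[-bad, ], sig[-bad, ], ignore_attr = TRUE)
  expect_equal(out$signal[7, ], (sig[6, ] + sig[8, ]) / 2,
               ignore_attr = TRUE)
})
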