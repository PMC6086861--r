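test_that("block covariance expands targets exactly in the independence and single-block cases", {
  part <- toy_partition(c(A = 5L, B = 5L))
  z0 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(unname(build_block_covariance(part, z0)), diag(10),
               ignore_attr = TRUE)

  z <- z0; z["A", "A"] <- 0.3
  cv <- build_block_covariance(part, z)
  inside <- cv[1:5, 1:5][upper.tri(diag(5))]
  expect_equal(unname(inside), rep(tanh(0.3), 10), tolerance = 1e-12)
  expect_true(all(cv[1:5, 6:10] == 0))
  expect_false(attr(cv, "repair")$repaired)
})

test_that("infeasible block specs are repaired to a nearby positive-definite matrix", {
  # two strongly coherent systems forced to be mutually uncorrelated is
  # jointly infeasible once cross terms are involved; force it harder by
  # making one block strongly negative inside
  part <- toy_partition(c(A = 6L, B = 6L))
  z <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  z["A", "A"] <- -0.5   # mean pairwise r = -0.46 among 6 ROIs: not PD
  cv <- build_block_covariance(part, z)
  expect_true(attr(cv, "repair")$repaired)
  expect_gt(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(unname(diag(cv)), rep(1, 12))
  blk <- cv[1:6, 1:6][upper.tri(diag(6))]
  # repaired block mean stays near the closest feasible value (-1/5 for
  # an equicorrelated 6-block), not the raw target
  expect_lt(mean(blk), -0.15)
  expect_error(build_block_covariance(part, matrix(c(0, 1, 0, 0), 2)),
               "symmetric")
})

test_that("time-series simulation is seed-deterministic and matches its covariance", {
  cv <- diag(6)
  cv[1, 2] <- cv[2, 1] <- 0.5
  a <- simulate_subject_timeseries(cv, 5000, seed = 42)
  b <- simulate_subject_timeseries(cv, 5000, seed = 42)
  expect_identical(a$signal, b$signal)
  r <- cor(a$signal)
  expect_gt(r[1, 2], 0.45); expect_lt(r[1, 2], 0.55)
  off <- r[upper.tri(r)][-1]   # pairs other than (1,2)
  expect_lt(max(abs(off)), 0.05)
  expect_error(simulate_subject_timeseries(matrix(c(1, 2, 2, 1), 2), 10, 1),
               "positive definite")
})

test_that("planted motion spikes have exact FD and are fully book-kept", {
  cv <- diag(8)
  ts <- simulate_subject_timeseries(cv, 240, seed = 3)
  inj <- inject_motion(ts, spike_rate = 0.1, spike_fd_mm = 1.6, seed = 9)
  fd <- compute_fd(inj$ts$motion)
  expect_true(length(inj$spike_frames) > 0)
  expect_equal(unname(fd[inj$spike_frames]),
               rep(1.6, length(inj$spike_frames)), tolerance = 1e-9)
  expect_lt(max(fd[-inj$spike_frames]), 0.8)

  none <- inject_motion(ts, spike_rate = 0, seed = 9)
  expect_length(none$spike_frames, 0)
  expect_lt(max(compute_fd(none$ts$motion)), 0.8)
})

test_that("behavior coupling hits its target correlation", {
  design <- data.frame(subject = sprintf("s%04d", 1:2000),
                       group = rep(c("I", "NI"), 1000))
  dfc <- rnorm(2000)
  d <- simulate_behavior(design, dfc, coupling = 0.4, seed = 5)
  r <- cor(dfc, d$inattention_t2 - d$inattention_t1)
  expect_gt(r, 0.36); expect_lt(r, 0.44)

  d0 <- simulate_behavior(design, dfc, coupling = 0, seed = 6)
  expect_lt(abs(cor(dfc, d0$inattention_t2 - d0$inattention_t1)),
            2 / sqrt(2000))

  d1 <- simulate_behavior(design, dfc, coupling = 1, seed = 7)
  expect_equal(cor(dfc, d1$inattention_t2 - d1$inattention_t1), 1,
               tolerance = 1e-12)

  expect_error(simulate_behavior(design, dfc[1:10], 0.4), "subjects")
})

test_that("cohort simulation is reproducible and loads back through the pipeline reader", {
  cfg <- synthetic_config(n_per_group = c(I = 3L, NI = 2L), n_frames = 64L,
                          roi_count = 16L, seed = 21L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$ground_truth, co2$ground_truth)
  expect_identical(co1$sessions[[1]]$signal, co2$sessions[[1]]$signal)
  expect_length(co1$sessions, 10L)

  dir <- withr::local_tempdir()
  write_cohort(co1, dir)
  bundle <- load_inputs(dir)
  expect_length(bundle$sessions, 10L)
  expect_equal(nrow(bundle$design), 5L)
  expect_equal(bundle$sessions[[1]]$signal, co1$sessions[[1]]$signal,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("empirical block means converge to the generating spec", {
  part <- default_partition(32)
  sys <- levels(part$system)
  z <- matrix(0.1, 8, 8, dimnames = list(sys, sys))
  diag(z) <- 0.3
  z["SVN", "SVN"] <- 0.45
  cv <- build_block_covariance(part, z)
  ts <- simulate_subject_timeseries(cv, 5000, seed = 13)
  bs <- block_summary(fc_matrix(ts), part)
  expect_lt(max(abs(bs$mean_z - z)), 0.05)
})
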