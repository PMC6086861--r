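test_that("residualization satisfies the OLS normal equations", {
  set.seed(30)
  y <- rnorm(29)
  covs <- data.frame(age = rnorm(29), scanner = factor(sample(c("a", "b"),
                                                              29, TRUE)))
  r <- residualize(y, covs)
  x <- model.matrix(~ ., covs)
  expect_lt(max(abs(crossprod(x, r))), 1e-8)

  # orthogonal covariate: residuals are the centered values
  v <- rep(c(-1, 1), 10)
  orth <- data.frame(c1 = rep(c(1, 1, -1, -1), 5))
  expect_equal(residualize(v, orth), v - mean(v), tolerance = 1e-12)

  # exact linear function: residuals vanish
  z <- rnorm(20)
  expect_equal(residualize(3 + 2 * z, data.frame(z = z)), rep(0, 20),
               tolerance = 1e-10)

  expect_error(residualize(y, data.frame(a = covs$age, b = 2 * covs$age)),
               "rank")
})

test_that("the interaction statistic is the pooled t on adjusted change scores", {
  st <- interaction_statistic(c(2, 1, 3, 0, 1, -1), rep(c("A", "B"), each = 3))
  expect_equal(st$t, 2 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$F, st$t^2)
  expect_equal(unname(st$group_means), c(2, 0))

  same <- interaction_statistic(c(1, 2, 3, 4, 1, 2, 3, 4),
                                rep(c("A", "B"), each = 4))
  expect_equal(same$t, 0)

  # a covariate unrelated to outcome and group barely moves the statistic
  set.seed(31)
  n <- 2000
  delta <- rnorm(n) + rep(c(0.2, 0), each = n / 2)
  grp <- rep(c("A", "B"), each = n / 2)
  noise_cov <- data.frame(u = rnorm(n))
  t_raw <- interaction_statistic(delta, grp)$t
  t_adj <- interaction_statistic(delta, grp, noise_cov)$t
  expect_lt(abs(t_raw - t_adj), 0.15)
})

test_that("permutation p-values are exact at the floor and reproducible", {
  set.seed(32)
  delta <- c(rep(10, 6), rnorm(8))     # overwhelming effect
  grp <- rep(c("A", "B"), c(6, 8))
  covs <- data.frame(age = rnorm(14))
  r <- permutation_interaction_test(delta, grp, covs, n_perms = 500, seed = 7)
  expect_equal(r$p, 1 / 501)
  r2 <- permutation_interaction_test(delta, grp, covs, n_perms = 500, seed = 7)
  expect_identical(r$p, r2$p)

  # small covariate-free designs are enumerated exactly
  re <- permutation_interaction_test(c(3, 2.5, 2, 0.1, 0, -0.4),
                                     rep(c("A", "B"), each = 3),
                                     n_perms = 100, seed = 1)
  expect_true(re$exact)
  expect_equal(re$n_perms, choose(6, 3))
  expect_equal(re$p, 2 / 20)   # only the observed split and its mirror are as extreme
})

test_that("permutation p is invariant to sign flips and monotone transforms of the outcome scale", {
  set.seed(33)
  delta <- rnorm(20) + rep(c(0.8, 0), each = 10)
  grp <- factor(rep(c("A", "B"), each = 10))
  covs <- data.frame(age = rnorm(20))
  r1 <- permutation_interaction_test(delta, grp, covs, n_perms = 300, seed = 5)
  rflip <- permutation_interaction_test(delta, factor(grp, levels = c("B", "A")),
                                        covs, n_perms = 300, seed = 5)
  expect_equal(rflip$statistic, -r1$statistic, tolerance = 1e-12)
  expect_equal(rflip$p, r1$p)

  # affine rescaling of the outcome leaves t and p unchanged
  rscale <- permutation_interaction_test(delta * 3.2, grp, covs,
                                         n_perms = 300, seed = 5)
  expect_equal(rscale$statistic, r1$statistic, tolerance = 1e-10)
  expect_equal(rscale$p, r1$p)
})

test_that("Freedman-Lane converges to the unadjusted test when covariates are null", {
  set.seed(34)
  n <- 400
  delta <- rnorm(n) + rep(c(0.3, 0), each = n / 2)
  grp <- rep(c("A", "B"), each = n / 2)
  covs <- data.frame(u = rnorm(n))
  t_adj <- interaction_statistic(delta, grp, covs)$t
  t_un <- interaction_statistic(delta, grp)$t
  expect_lt(abs(t_adj - t_un), 0.1)
})

test_that("the suite tests every block and metric outcome and flags the planted block", {
  set.seed(35)
  cfg <- synthetic_config(n_per_group = c(I = 9L, NI = 7L), n_frames = 200L,
                          roi_count = 32L, motion_spike_rate = 0, seed = 71L)
  cb <- cohort_block_deltas(cfg, planted_delta = 0.25)
  res <- run_interaction_suite(block_tables = cb$blocks,
                               design = cb$cohort$design,
                               n_perms = 500, seed = 2)
  expect_equal(nrow(res), 36L)   # 8 intra + 28 inter blocks
  svn <- res[res$outcome == "SVN-SVN", ]
  expect_true(svn$sig_fc)
  others <- res[res$outcome != "SVN-SVN", ]
  expect_lt(median(abs(others$statistic)), 2)

  # determinism of the whole result table
  res2 <- run_interaction_suite(block_tables = cb$blocks,
                                design = cb$cohort$design,
                                n_perms = 500, seed = 2)
  expect_identical(res, res2)
})

test_that("brain-behavior correlation recovers exact and null relationships", {
  set.seed(36)
  x <- rnorm(40)
  r1 <- brain_behavior_correlation(x, x)
  expect_equal(r1$r, 1)
  expect_equal(r1$df, 38L)

  y <- rnorm(2000); z <- rnorm(2000)
  r0 <- brain_behavior_correlation(y, z)
  expect_lt(abs(r0$r), 0.05)

  covs <- data.frame(age = rnorm(40))
  rc <- brain_behavior_correlation(x, x + 0.5 * covs$age, covs)
  expect_equal(rc$df, 40L - 2L - 1L)
  expect_error(brain_behavior_correlation(x, rep(1, 40)), "constant")
})

test_that("generator coupling is recovered by the correlation estimator", {
  set.seed(37)
  rs <- replicate(200, {
    dfc <- rnorm(29)
    design <- data.frame(subject = sprintf("s%02d", 1:29),
                         group = rep(c("I", "NI"), c(18, 11)))
    d <- simulate_behavior(design, dfc, coupling = 0.4,
                           seed = sample.int(1e6, 1))
    brain_behavior_correlation(dfc, d$inattention_t2 - d$inattention_t1)$r
  })
  expect_lt(abs(mean(rs) - 0.4), 0.05)
})
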