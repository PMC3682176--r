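test_that("behavioural simulation is deterministic and matches its targets", {
  a <- simulate_iq(33, seed = 7)
  b <- simulate_iq(33, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_iq(33, seed = 8)))
  validate_iq_table(a)
  # sample means within 3 standard errors of the configured means
  expect_lt(abs(mean(a$viq_t1) - 113), 3 * 15.1 / sqrt(33) + 0.5)
  expect_lt(abs(mean(a$piq_t1) - 108), 3 * 12.3 / sqrt(33) + 0.5)
})

test_that("perfect retest correlation with zero change SD collapses the changes", {
  tab <- simulate_iq(20, seed = 3,
                     retest_r = c(viq = 1, piq = 1),
                     change_sd = c(viq = 0, piq = 0))
  # constant shift up to integer rounding of the two draws
  expect_lte(diff(range(tab$d_viq)), 1)
  expect_lte(diff(range(tab$d_piq)), 1)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulate_iq(2, seed = 1), "at least 3")
  expect_error(simulate_iq(10, seed = 1, retest_r = c(viq = 1.2, piq = 0.5)),
               "retest_r")
  expect_error(ground_truth(noise_sd = -1), "noise_sd")
  expect_error(ground_truth(shape = c(8, 8, 8), center_v = c(8, 8, 8)),
               "outside the grid")
  expect_error(ground_truth(shape = c(8, 8, 8), center_v = c(4, 4, 4),
                            center_p = c(4, 4, 4)), "disjoint")
})

test_that("volume generation is bit-identical for a fixed seed", {
  truth <- ground_truth(shape = c(8, 8, 8))
  tab <- simulate_iq(5, seed = 11)
  v1 <- simulate_volumes(tab, truth, seed = 12)
  v2 <- simulate_volumes(tab, truth, seed = 12)
  expect_identical(v1$t1, v2$t1)
  expect_identical(v1$t2, v2$t2)
  expect_false(identical(v1$t1, simulate_volumes(tab, truth, seed = 13)$t1))
})

test_that("noise-free volumes follow the closed-form generative model", {
  tab <- toy_iq_table(d_viq = c(2, -1, 0, 3), d_piq = c(1, 1, -2, 0))
  truth <- ground_truth(shape = c(8, 8, 8), noise_sd = 0, age_slope = -0.004)

  # slopes zero: difference image is exactly twice the age effect
  t0 <- truth; t0$slope_v <- 0; t0$slope_p <- 0
  v0 <- simulate_volumes(tab, t0, seed = 5)
  for (i in seq_len(4))
    expect_equal(v0$t2[, , , i] - v0$t1[, , , i],
                 array(2 * -0.004, c(8, 8, 8)))

  # with a planted slope the change at the region centre is
  # 2*age + 2*slope*d exactly
  v1 <- simulate_volumes(tab, truth, seed = 5)
  ctr <- truth$center_v
  d <- v1$t2[ctr[1], ctr[2], ctr[3], ] - v1$t1[ctr[1], ctr[2], ctr[3], ]
  expect_equal(d, 2 * -0.004 + 2 * truth$slope_v * tab$d_viq)
})

test_that("voxel-wise regression recovers the planted slope under noise", {
  tab <- simulate_iq(33, seed = 21)
  truth <- ground_truth(shape = c(10, 10, 10), slope_v = 8e-4, slope_p = 0,
                        noise_sd = 0.02)
  vols <- simulate_volumes(tab, truth, seed = 22)
  ctr <- truth$center_v
  delta <- vols$t2[ctr[1], ctr[2], ctr[3], ] - vols$t1[ctr[1], ctr[2], ctr[3], ]
  fit <- summary(lm(delta ~ tab$d_viq))
  est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
  expect_lt(abs(est - 2 * 8e-4), 3 * se)
})

test_that("theoretical peak R2 has its boundary values and matches Monte Carlo", {
  tab <- simulate_iq(10, seed = 31)
  noiseless <- ground_truth(shape = c(6, 6, 6), center_v = c(2, 3, 3), center_p = c(5, 3, 3), noise_sd = 0)
  expect_equal(theoretical_r2(noiseless, tab, "viq"), 1)
  flat <- ground_truth(shape = c(6, 6, 6), center_v = c(2, 3, 3), center_p = c(5, 3, 3), slope_v = 0)
  expect_equal(theoretical_r2(flat, tab, "viq", n_rep = 50), 0)
  dead <- ground_truth(shape = c(6, 6, 6), center_v = c(2, 3, 3), center_p = c(5, 3, 3), slope_v = 0, noise_sd = 0)
  expect_error(theoretical_r2(dead, tab, "viq"), "zero")

  # Monte-Carlo oracle: empirical R^2 of density change on IQ change at
  # the planted peak over 10,000 simulated subjects
  big <- simulate_iq(10000, seed = 32)
  truth <- ground_truth(shape = c(6, 6, 6), center_v = c(2, 3, 3), center_p = c(5, 3, 3), slope_v = 6e-4, noise_sd = 0.015)
  vols <- simulate_volumes(big, truth, seed = 33)
  ctr <- truth$center_v
  delta <- vols$t2[ctr[1], ctr[2], ctr[3], ] - vols$t1[ctr[1], ctr[2], ctr[3], ]
  emp <- summary(lm(delta ~ big$d_viq))$r.squared
  theo <- theoretical_r2(truth, big, "viq", n_rep = 400, seed = 34)
  expect_lt(abs(emp - theo), 0.02)
})

test_that("slope calibration hits a requested theoretical R2", {
  tab <- simulate_iq(33, seed = 41)
  truth <- ground_truth(shape = c(10, 10, 10))
  truth$slope_v <- slope_for_r2(truth, tab$d_viq, 0.5, n_rep = 300, seed = 42)
  got <- theoretical_r2(truth, tab, "viq", n_rep = 300, seed = 42)
  expect_equal(got, 0.5, tolerance = 0.02)
})
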