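test_that("axis profiles collapse the map as specified", {
  m <- matrix(0, 25, 40)
  m[, c(10, 20, 30)] <- 1
  prof <- axis_profile(m, "horizontal")
  expect_equal(prof$values[c(10, 20, 30)], rep(25, 3))
  expect_equal(sum(prof$values), sum(m))
  expect_true(all(prof$values[-c(10, 20, 30)] == 0))
  # transpose symmetry
  pv <- axis_profile(t(m), "vertical")
  expect_equal(pv$values, prof$values)
  # conservation on a random map
  set.seed(1)
  r <- matrix(runif(300), 15, 20)
  expect_equal(sum(axis_profile(r, "vertical")$values), sum(r))
})

test_that("autocorrelation matches hand evaluation and the n^2 oracle", {
  ac <- autocorrelation(c(1, 0, 1, 0), 2)
  expect_equal(ac$values, c(2, 0, 1))
  set.seed(2)
  for (n in c(17, 128, 512)) {
    x <- runif(n)
    m_max <- n %/% 2
    ac <- autocorrelation(x, m_max)
    expect_equal(ac$values, oracle_autocorr(x, m_max), tolerance = 1e-12)
    expect_equal(ac$values[1], sum(x^2))
    expect_equal(max(ac$values), ac$values[1])
  }
  expect_error(autocorrelation(c(1, 2, 3), 3), "smaller")
  # impulse comb with period 10 has local maxima at multiples of 10
  comb <- rep(c(1, rep(0, 9)), 12)
  ac <- autocorrelation(comb, 40)
  peaks <- which(ac$values > 0.5 * max(ac$values)) - 1
  expect_equal(peaks, c(0, 10, 20, 30, 40))
})

test_that("grid spacing is recovered within 2 percent across scales", {
  for (d in c(4, 6.5, 10, 17.3, 30)) {
    gm <- synth_grid_map(d, round(36 * d), round(50 * d))
    ex <- ecgdigitizer:::estimate_spacing_from_map(gm, "horizontal")
    ey <- ecgdigitizer:::estimate_spacing_from_map(gm, "vertical")
    expect_lt(abs(ex$d_px - d) / d, 0.02, label = sprintf("x d = %g", d))
    expect_lt(abs(ey$d_px - d) / d, 0.02, label = sprintf("y d = %g", d))
    expect_lt(abs(ex$d_px - ey$d_px) / d, 0.01)
  }
})

test_that("non-integer spacing is recovered with subpixel precision", {
  gm <- synth_grid_map(23.7, 500, 900)
  est <- ecgdigitizer:::estimate_spacing_from_map(gm, "horizontal")
  expect_lt(abs(est$d_px - 23.7), 0.2)
})

test_that("spacing estimation is scale invariant and fails on flat input", {
  gm <- synth_grid_map(10, 300, 400)
  prof <- axis_profile(gm, "horizontal")
  ac1 <- autocorrelation(prof, 150)
  est1 <- estimate_spacing(ac1, c(3, 40))
  prof$values <- prof$values * 7.3
  ac2 <- autocorrelation(prof, 150)
  est2 <- estimate_spacing(ac2, c(3, 40))
  expect_equal(est1$d_px, est2$d_px)
  flat <- autocorrelation(rep(1, 400), 150)
  expect_error(estimate_spacing(flat, c(3, 40)),
               class = "calibration_failure")
})

test_that("physical calibration follows the paper constants", {
  cal <- to_physical(10, 10, speed_mm_per_s = 50, gain_mm_per_mV = 10)
  expect_equal(cal$seconds_per_px, 0.002)
  expect_equal(cal$mV_per_px, 0.01)
  expect_equal(1 / cal$seconds_per_px, 500) # px per second
  expect_equal(1 / cal$mV_per_px, 100)      # px per mV
  cal2 <- to_physical(20, 20, 50, 10)
  expect_equal(cal2$seconds_per_px, cal$seconds_per_px / 2)
  expect_equal(cal2$mV_per_px, cal$mV_per_px / 2)
  expect_error(to_physical(-1, 10), "positive")
})
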