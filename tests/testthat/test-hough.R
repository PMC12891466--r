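test_that("axis-aligned lines map to the expected Hough maxima", {
  m <- matrix(0, 40, 60)
  m[25, ] <- 1 # horizontal line at row 25 (0-based y = 24)
  acc <- hough_transform(m, seq(-pi / 4, 3 * pi / 4, by = pi / 360))
  peak <- arrayInd(which.max(acc$votes), dim(acc$votes))
  # peak within one angular bin of the analytic location
  expect_equal(acc$theta_axis[peak[1]], pi / 2, tolerance = pi / 300)
  expect_equal(acc$rho_axis[peak[2]], 24, tolerance = 1)

  m2 <- matrix(0, 40, 60)
  m2[, 31] <- 1 # vertical line at column 31 (x = 30)
  acc2 <- hough_transform(m2, seq(-pi / 4, 3 * pi / 4, by = pi / 360))
  peak2 <- arrayInd(which.max(acc2$votes), dim(acc2$votes))
  expect_equal(acc2$theta_axis[peak2[1]], 0, tolerance = pi / 300)
  expect_equal(acc2$rho_axis[peak2[2]], 30, tolerance = 1)
})

test_that("voting is linear and equals brute-force accumulation", {
  set.seed(11)
  thetas <- seq(-pi / 4, 3 * pi / 4, length.out = 37)
  for (rep in 1:3) {
    m <- matrix(runif(64 * 64), 64, 64) * (matrix(runif(64 * 64), 64) < 0.2)
    acc <- hough_transform(m, thetas, rho_resolution = 1)
    oracle <- oracle_hough(m, thetas, min(acc$rho_axis), 1,
                           length(acc$rho_axis))
    expect_equal(unname(acc$votes), oracle, tolerance = 1e-9)
  }
  # linearity: transform of a sum is the sum of transforms
  m1 <- matrix(runif(32 * 32), 32) * 0.5
  m2 <- matrix(runif(32 * 32), 32) * 0.5
  a1 <- hough_transform(m1, thetas)$votes
  a2 <- hough_transform(m2, thetas)$votes
  a12 <- hough_transform(m1 + m2, thetas)$votes
  expect_equal(a12, a1 + a2, tolerance = 1e-9)
  # empty map -> all-zero accumulator, not an error
  expect_true(all(hough_transform(matrix(0, 16, 16), thetas)$votes == 0))
  expect_error(hough_transform(matrix(2, 4, 4), thetas), "\\[0, 1\\]")
})

test_that("angle-angle transform of a constant accumulator is zero", {
  acc <- structure(list(theta_axis = seq(0, 1, by = 0.1),
                        rho_axis = seq(0, 50), votes = matrix(3, 11, 51)),
                   class = "hough_accumulator")
  aa <- angle_angle_transform(acc)
  expect_true(all(abs(aa) < 1e-9))
  acc$rho_axis <- 1
  acc$votes <- matrix(1, 11, 1)
  expect_error(angle_angle_transform(acc), "rho bins")
})

test_that("an unrotated grid yields angle-angle maxima at 0 and pi/2", {
  gm <- synth_grid_map(5, 120, 160)
  thetas <- seq(-pi / 4, 3 * pi / 4, by = 0.5 * pi / 180)
  acc <- hough_transform(gm, thetas)
  acc$votes <- ecgdigitizer:::sharpen_accumulator(acc$votes)
  aa <- angle_angle_transform(acc)
  spread_ok <- abs(outer(thetas, thetas, `-`)) <= 25 * pi / 180
  aa[!spread_ok] <- -Inf
  p1 <- arrayInd(which.max(aa), dim(aa))
  ang1 <- (thetas[p1[1]] + thetas[p1[2]]) / 2
  # mask out the first family's neighbourhood, find the second
  dang <- outer(thetas, thetas, function(a, b) (a + b) / 2)
  dd <- abs(((dang - ang1) + pi / 2) %% pi - pi / 2)
  aa2 <- aa
  aa2[dd < pi / 4] <- -Inf
  p2 <- arrayInd(which.max(aa2), dim(aa2))
  ang2 <- (thetas[p2[1]] + thetas[p2[2]]) / 2
  angs <- sort(c(ang1, ang2))
  expect_equal(angs[1], 0, tolerance = 0.01)
  expect_equal(angs[2], pi / 2, tolerance = 0.01)
})

test_that("a known rotation displaces the detected families accordingly", {
  gm <- synth_grid_map(5, 150, 200)
  th <- 5 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 30), c(sin(th), cos(th), 5), c(0, 0, 1))
  gmr <- ecgdigitizer:::warp_image(gm, rot, 220, 260, "bilinear")
  fams <- find_line_families(gmr)
  angs <- vapply(fams, function(f) (f$theta_rho_min + f$theta_rho_max) / 2, 0)
  expect_equal(angs[1] * 180 / pi, 95, tolerance = 0.5)
  expect_equal(angs[2] * 180 / pi, 5, tolerance = 0.5)
})

test_that("degenerate maps raise a dewarp failure", {
  expect_error(find_line_families(matrix(0, 50, 50)),
               class = "dewarp_failure")
  set.seed(1)
  expect_error(find_line_families(matrix(runif(80 * 80), 80, 80)),
               class = "dewarp_failure")
})
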