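test_that("pure rotations are recovered within 0.2 degrees", {
  gm <- synth_grid_map(5, 220, 320)
  for (deg in c(-40, -15, 0, 8, 40)) {
    th <- deg * pi / 180
    rot <- rbind(c(cos(th), -sin(th), 120), c(sin(th), cos(th), 40),
                 c(0, 0, 1))
    gmr <- ecgdigitizer:::warp_image(gm, rot, 560, 620, "bilinear")
    fams <- find_line_families(gmr)
    ang_v <- (fams[[2]]$theta_rho_min + fams[[2]]$theta_rho_max) / 2
    expect_lt(abs(ang_v * 180 / pi - deg), 0.2,
              label = sprintf("rotation %d", deg))
  }
})

test_that("random homographies are undone to sub-degree gridline alignment", {
  devs <- homography_recovery_study(50)
  expect_lt(median(devs), 0.5)
})

test_that("rectification composes with the true warp to near-similarity", {
  gm <- synth_grid_map(6, 240, 360)
  hm <- random_homography(360, 240, 12, seed = 77)
  corners <- apply_homography(hm, rbind(c(0, 0), c(359, 0), c(359, 239),
                                        c(0, 239)))
  out_w <- ceiling(max(corners[, 1])) + 1
  out_h <- ceiling(max(corners[, 2])) + 1
  gmw <- ecgdigitizer:::warp_image(gm, hm, out_h, out_w, "bilinear")
  fams <- find_line_families(gmw)
  stack <- array(0, c(out_h, out_w, 4))
  stack[, , 2] <- gmw
  stack[, , 3] <- gmw
  dw <- rectify(array(0.5, c(out_h, out_w, 3)), stack, fams,
                equalize_axes = FALSE)
  # total transform: original -> warped -> rectified should be close to a
  # similarity: straight grid lines stay straight and orthogonal
  comp <- dw$homography %*% hm
  pts <- expand.grid(x = seq(40, 320, by = 70), y = seq(40, 200, by = 54))
  mapped <- apply_homography(comp, as.matrix(pts))
  fitx <- lm(mapped[, 1] ~ pts$x + pts$y)
  fity <- lm(mapped[, 2] ~ pts$x + pts$y)
  expect_lt(max(abs(c(residuals(fitx), residuals(fity)))), 1)
})

test_that("rectifying an already-rectified sample barely moves pixels", {
  gm <- synth_grid_map(6, 220, 330)
  fams <- find_line_families(gm)
  stack <- array(0, c(220, 330, 4))
  stack[, , 2] <- gm
  stack[, , 3] <- gm
  dw <- rectify(array(0.5, c(220, 330, 3)), stack, fams,
                equalize_axes = FALSE, crop_margin_mm = 100)
  comp <- dw$homography
  pts <- as.matrix(expand.grid(x = c(30, 160, 300), y = c(30, 110, 190)))
  mapped <- apply_homography(comp, pts)
  shift <- mapped - pts
  # allow a global translation; deviations from it stay under a pixel
  expect_lt(max(abs(sweep(shift, 2, colMeans(shift)))), 1)
})

test_that("the crop keeps the signal mass with a clear margin", {
  rt <- fix_oracle_roundtrip()
  rs <- rt$render
  probs <- ground_truth_probs(rs)
  fams <- find_line_families(probs[, , 2])
  dw <- rectify(rs$image, probs, fams)
  # probability mass is preserved through warp + crop (interpolation may
  # move mass across the 0.5 threshold but must not discard it)
  expect_gt(sum(dw$probs[, , 3]) / sum(probs[, , 3]), 0.9)
  # every super-threshold signal pixel sits well inside the crop
  sig <- which(dw$probs[, , 3] > 0.5, arr.ind = TRUE)
  d_ref <- dw$d_provisional[1]
  expect_gt(min(sig[, 1]), 0.3 * 10 * d_ref)
  expect_gt(min(sig[, 2]), 0.3 * 10 * d_ref)
  expect_lt(max(sig[, 1]), nrow(dw$probs) - 0.3 * 10 * d_ref)
  expect_lt(max(sig[, 2]), ncol(dw$probs) - 0.3 * 10 * d_ref)
})

test_that("degenerate inputs fall back to the rotation path", {
  blank <- matrix(0, 60, 60)
  expect_equal(estimate_rotation(blank), 0)
  gm <- synth_grid_map(5, 200, 300)
  th <- -7 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 40), c(sin(th), cos(th), 30), c(0, 0, 1))
  gmr <- ecgdigitizer:::warp_image(gm, rot, 280, 360, "bilinear")
  est <- estimate_rotation(gmr)
  expect_lt(abs(est * 180 / pi - (-7)), 1)
})
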