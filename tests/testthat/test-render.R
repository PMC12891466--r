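test_that("calibration truth follows dpi", {
  sig <- simulate_ecg(12, 10, 100, seed = 1)
  rs <- render_paper(sig, render_config(dpi = 254, speed_mm_per_s = 50,
                                        row_mm = 20, seed = 1))
  expect_equal(rs$calibration_truth, 10)
  expect_equal(rs$homography, diag(3))
  expect_equal(dim(rs$class_mask), dim(rs$image)[1:2])
  expect_equal(dim(rs$lead_text_mask), dim(rs$image)[1:2])
})

test_that("a flat zero signal renders 13 straight lead segments in 3x4+rhythm", {
  flat <- simulate_ecg(12, 10, 100, seed = 1)
  flat$samples[] <- 0
  rs <- render_paper(flat, render_config(dpi = 60, speed_mm_per_s = 25))
  sig_rows <- which(rowSums(rs$class_mask == 2L) > 0)
  # one perfectly horizontal trace per strip row (3 grid strips + rhythm);
  # adjacent panels in a strip abut, as on real paper, so each of the 13
  # lead segments is a straight run across its own panel window
  expect_equal(length(sig_rows), 4)
  p <- rs$truth$panels
  expect_equal(nrow(p), 13)
  for (i in seq_len(nrow(p))) {
    seg <- rs$class_mask[p$r0[i]:p$r1[i], p$c0[i]:(p$c1[i] - 1L)] == 2L
    rows_hit <- which(rowSums(seg) > 0)
    expect_equal(length(rows_hit), 1, label = paste("lead", p$lead[i]))
    expect_equal(sum(seg[rows_hit, ]), ncol(seg))
  }
})

test_that("a 1 mV calibration pulse spans the expected pixel height", {
  pulse <- simulate_ecg(12, 10, 500, seed = 1)
  pulse$samples[] <- 0
  t <- (seq_len(nrow(pulse$samples)) - 1) / pulse$rate
  pulse$samples[t >= 0.4 & t < 0.9, ] <- 1 # 1 mV square pulse in every lead
  rs <- render_paper(pulse, render_config(dpi = 254, speed_mm_per_s = 50,
                                          gain_mm_per_mV = 10))
  p <- rs$truth$panels
  i <- which(p$lead == "I")
  band <- rs$class_mask[p$r0[i]:p$r1[i], p$c0[i]:(p$c1[i] - 1)]
  rows <- which(rowSums(band == 2L) > 0)
  # 1 mV x 10 mm/mV x 10 px/mm = 100 px between baseline and pulse top
  expect_lt(abs(diff(range(rows)) - 100), 2)
})

test_that("signal pixels carry the configured line color", {
  rs <- fix_render()
  sel <- rs$class_mask == 2L
  for (ch in 1:3) {
    expect_true(all(rs$image[, , ch][sel] == rs$config$line_color[ch]))
  }
  expect_setequal(sort(unique(as.vector(rs$class_mask))), 0:3)
  expect_setequal(sort(unique(as.vector(rs$lead_text_mask))), 0:12)
})

test_that("rendering is deterministic and validates its inputs", {
  sig <- simulate_ecg(12, 10, 100, seed = 2)
  cfg <- render_config(dpi = 60)
  expect_identical(render_paper(sig, cfg)$image, render_paper(sig, cfg)$image)
  short <- simulate_ecg(12, 2, 100, seed = 2)
  expect_error(render_paper(short, cfg), "shorter")
  expect_error(render_paper(sig, render_config(layout_name = "nope")),
               "unknown layout")
  expect_error(render_config(dpi = -1), "dpi")
})

test_that("perspective warp records its homography and is invertible", {
  rs <- fix_render()
  expect_identical(apply_perspective(rs, max_tilt_deg = 0), rs)

  ws <- apply_perspective(rs, max_tilt_deg = 12, seed = 5,
                          background_style = "noise")
  expect_false(identical(dim(ws$image), dim(rs$image)))
  # paper corners map exactly through the recorded homography
  expect_equal(ws$paper_corners,
               apply_homography(ws$homography, rs$paper_corners))
  # inverse-warping the warped mask recovers the original except borders
  back <- ecgdigitizer:::warp_image(ws$class_mask + 0, solve(ws$homography),
                                    nrow(rs$class_mask), ncol(rs$class_mask),
                                    "nearest")
  inner <- 5:(nrow(rs$class_mask) - 5)
  innc <- 5:(ncol(rs$class_mask) - 5)
  agree <- mean(back[inner, innc] == rs$class_mask[inner, innc])
  expect_gt(agree, 0.98)
  # determinism
  ws2 <- apply_perspective(rs, max_tilt_deg = 12, seed = 5,
                           background_style = "noise")
  expect_identical(ws$image, ws2$image)
})

test_that("training crops are aligned, deterministic and pad small images", {
  rs <- fix_render()
  cr <- make_training_crop(rs, 64, seed = 2)
  expect_equal(dim(cr$image), c(64, 64, 3))
  expect_equal(dim(cr$class_mask), c(64, 64))
  expect_identical(cr, make_training_crop(rs, 64, seed = 2))

  # crop of the mask equals mask of the crop: signal pixels in the crop
  # still carry the line color
  sel <- cr$class_mask == 2L
  expect_true(all(cr$image[, , 1][sel] == rs$config$line_color[1]))

  # identity crop
  full <- make_training_crop(rs, min(dim(rs$class_mask)), seed = 1)
  expect_equal(dim(full$class_mask), rep(min(dim(rs$class_mask)), 2))

  # padding path
  big <- make_training_crop(rs, max(dim(rs$class_mask)) + 10, seed = 1)
  expect_equal(dim(big$class_mask), rep(max(dim(rs$class_mask)) + 10, 2))
  expect_true(all(big$class_mask %in% 0:3))
})

test_that("fading augmentation darkens the image but leaves masks alone", {
  rs <- fix_render()
  fd <- apply_fading(rs, strength = 0.3, seed = 1)
  expect_identical(fd$class_mask, rs$class_mask)
  expect_lte(max(fd$image - rs$image), 1e-12)
  expect_lt(mean(fd$image), mean(rs$image))
})
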