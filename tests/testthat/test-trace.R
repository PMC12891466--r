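test_that("connected components match extent and a flood-fill oracle", {
  m <- matrix(0, 20, 40)
  m[5, 3:12] <- 1
  m[15, 20:35] <- 1
  comps <- extract_components(m, min_mass = 2)
  expect_length(comps, 2)
  expect_equal(sort(vapply(comps, function(c) c$c_min, 0)), c(3, 20))
  expect_equal(sort(vapply(comps, function(c) c$c_max, 0)), c(12, 35))

  # diagonal stroke: single 8-connected component with endpoints at its ends
  d <- matrix(0, 30, 30)
  for (i in 1:25) d[i + 2, i + 1] <- 1
  cd <- extract_components(d, min_mass = 2)
  expect_length(cd, 1)
  expect_equal(cd[[1]]$left_row, 3)
  expect_equal(cd[[1]]$right_row, 27)

  # oracle equality on random masks
  set.seed(21)
  for (rep in 1:5) {
    r <- matrix(runif(64 * 64) < 0.25, 64, 64)
    ours <- ecgdigitizer:::label_components8(r)
    oracle <- oracle_label8(r)
    expect_equal(max(ours), max(oracle))
    # same partition (labels may be permuted)
    expect_equal(length(unique(paste(ours[r], oracle[r]))), max(oracle))
  }
  expect_length(extract_components(matrix(0, 8, 8)), 0)
})

test_that("snipping separates bridged strokes and leaves solid blocks alone", {
  m <- matrix(0, 21, 40)
  m[8, 2:19] <- 0.9   # upper stroke
  m[14, 21:38] <- 0.9 # lower stroke
  m[8:14, 20] <- 0.9  # single-pixel-wide bridge
  comps <- extract_components(m, min_mass = 2)
  expect_length(comps, 1)
  parts <- snip_component(comps[[1]], m)
  expect_gte(length(parts), 2)
  # no pixels outside the original component were touched
  orig <- sort(comps[[1]]$rows + 1000 * comps[[1]]$cols)
  after <- sort(unlist(lapply(parts, function(p) p$rows + 1000 * p$cols)))
  expect_true(all(after %in% orig))

  solid <- matrix(0, 12, 12)
  solid[4:9, 3:10] <- 1
  sc <- extract_components(solid, min_mass = 2)
  out <- snip_component(sc[[1]], solid)
  expect_length(out, 1)
  expect_true(isTRUE(attr(out[[1]], "snip_failed")))
})

test_that("problematic components are recognized", {
  tall <- matrix(0, 60, 30)
  tall[10:50, 5:25] <- 0
  tall[10, 5:25] <- 1
  tall[50, 5:25] <- 1
  tall[10:50, 15] <- 1
  comp <- extract_components(tall, min_mass = 2)[[1]]
  expect_true(is_problematic(comp, band_height = 20))

  # a single-run diagonal is problematic only when it outgrows the band
  d <- matrix(0, 60, 60)
  for (i in 1:50) d[i + 2, i + 1] <- 1
  dc <- extract_components(d, min_mass = 2)[[1]]
  expect_true(is_problematic(dc, band_height = 30))
  expect_false(is_problematic(dc, band_height = 100))

  flat <- matrix(0, 20, 30)
  flat[10, 2:28] <- 1
  fc <- extract_components(flat, min_mass = 2)[[1]]
  expect_false(is_problematic(fc, band_height = 15))
})

test_that("collinear strokes merge into one left-to-right chain", {
  m <- matrix(0, 15, 60)
  m[8, 3:15] <- 1
  m[8, 22:35] <- 1
  m[8, 42:57] <- 1
  comps <- extract_components(m, min_mass = 2)
  expect_length(comps, 3)
  chains <- merge_components(comps)
  expect_length(chains, 1)
  expect_equal(vapply(chains[[1]], function(c) c$c_min, 0), c(3, 22, 42))
})

test_that("assignment cost equals the exhaustive-permutation minimum", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(2:7, 1)
    cost <- matrix(runif(n * n, 0, 100), n, n)
    sol <- ecgdigitizer:::jv_assign(cost)
    ours <- sum(cost[cbind(seq_len(n), sol)])
    expect_equal(ours, oracle_assignment_cost(cost), tolerance = 1e-9,
                 label = sprintf("rep %d n %d", rep, n))
    expect_equal(sort(sol), seq_len(n)) # a permutation
  }
})

test_that("an isolated distant speck self-matches and is dropped", {
  m <- matrix(0, 80, 60)
  m[60, 5:25] <- 1
  m[60, 35:55] <- 1
  m[6:7, 30:31] <- 1 # speck far above the lead band
  comps <- extract_components(m, min_mass = 2)
  expect_length(comps, 3)
  chains <- merge_components(comps)
  expect_length(chains, 1)
  rows_used <- unlist(lapply(chains[[1]], function(c) c$rows))
  expect_false(any(rows_used < 20))
})

test_that("traces convert rows to millivolts with NaN semantics", {
  m <- matrix(0, 30, 50)
  m[12, 5:45] <- 1
  m[, 25] <- 0 # one missing column
  comps <- extract_components(m, min_mass = 2)
  cal <- to_physical(10, 10, 25, 10)
  tr <- chain_to_trace(comps, m, cal, col_range = c(5, 45))
  expect_equal(tr$n_nan, 1)
  expect_true(is.na(tr$mv[tr$columns == 25]))
  expect_true(all(abs(tr$mv[!is.na(tr$mv)]) < 1e-9)) # constant -> zeros

  expect_warning(tr0 <- chain_to_trace(list(), m, cal, col_range = c(1, 10)),
                 "empty chain")
  expect_true(all(is.na(tr0$mv)))
})

test_that("a rendered ramp is recovered with its physical slope", {
  # 0.5 mV per second ramp rendered and re-extracted
  sig <- simulate_ecg(12, 10, 250, seed = 2)
  sig$samples[] <- 0
  t <- (seq_len(nrow(sig$samples)) - 1) / sig$rate
  sig$samples[, "II"] <- 0.5 * (t - 5) # rhythm lead carries the ramp
  rs <- render_paper(sig, render_config(dpi = 100, speed_mm_per_s = 25,
                                        seed = 2))
  probs <- ground_truth_probs(rs)
  p <- rs$truth$panels
  i <- which(p$lead == "II" & p$rhythm)
  band <- probs[p$r0[i]:p$r1[i], , 3]
  chains <- band_chains(band, band_height = nrow(band))
  cal <- to_physical(rs$calibration_truth, rs$calibration_truth, 25, 10)
  tr <- chain_to_trace(unlist(chains, recursive = FALSE), band, cal,
                       col_range = c(p$c0[i], p$c1[i] - 1))
  tt <- (tr$columns - p$c0[i]) * cal$seconds_per_px
  fit <- lm(tr$mv ~ tt)
  expect_lt(abs(coef(fit)[2] - 0.5) / 0.5, 0.02)
})

test_that("records resample traces preserving rate, length and gaps", {
  t_nat <- seq(0, 2, by = 0.002) # 500 Hz native
  v <- sin(2 * pi * t_nat)
  rec <- assemble_record(list(II = list(t = t_nat, mv = v)), duration_s = 2,
                         target_rate = 500, gap_fill_ms = 0)
  expect_equal(rec$samples[1:1000, "II"], v[1:1000], tolerance = 1e-9)

  rec2 <- assemble_record(list(II = list(t = t_nat, mv = v)), duration_s = 2,
                          target_rate = 1000)
  expect_equal(nrow(rec2$samples), 2000)
  expect_lt(max(abs(rec2$samples[, "II"] -
                      sin(2 * pi * (0:1999) / 1000)), na.rm = TRUE), 1e-3)

  # NaN fraction is preserved under same-rate resampling
  set.seed(4)
  v_na <- v
  v_na[sample(length(v), 100)] <- NA
  v_na[300:380] <- NA
  frac_in <- mean(is.na(v_na))
  rec3 <- assemble_record(list(II = list(t = t_nat, mv = v_na)),
                          duration_s = 2, target_rate = 500,
                          gap_fill_ms = 0)
  frac_out <- mean(is.na(rec3$samples[, "II"]))
  expect_lt(abs(frac_out - frac_in), 0.01)
  # short gaps are closed when gap filling is on; the long run stays NA
  rec4 <- assemble_record(list(II = list(t = t_nat, mv = v_na)),
                          duration_s = 2, target_rate = 500,
                          gap_fill_ms = 20)
  expect_true(all(is.na(rec4$samples[310:370, "II"])))
  expect_lt(mean(is.na(rec4$samples[, "II"])), frac_out)
  expect_error(assemble_record(list(), 1, target_rate = 0), "target_rate")
})

test_that("records round-trip through CSV and WFDB writers", {
  set.seed(5)
  m <- matrix(rnorm(400 * 3, sd = 0.4), 400, 3,
              dimnames = list(NULL, c("I", "II", "V1")))
  m[50:60, 2] <- NA
  rec <- structure(list(leads = colnames(m), samples = m, rate = 200,
                        duration_s = 2, calibration = NULL,
                        layout_name = "3x4", warnings = character()),
                   class = "ecg_record")
  csv <- tempfile(fileext = ".csv")
  write_record_csv(rec, csv)
  back <- read_record_csv(csv)
  expect_equal(back$samples, m, tolerance = 1e-6)
  expect_equal(back$rate, 200)

  pre <- tempfile()
  write_record_wfdb(rec, pre)
  wb <- read_record_wfdb(pre)
  expect_equal(wb$leads, rec$leads)
  expect_equal(wb$rate, 200)
  expect_true(all(is.na(wb$samples[50:60, 2])))
  expect_lt(max(abs(wb$samples - m), na.rm = TRUE), 1 / 200)
})
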