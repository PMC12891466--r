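test_that("alignment recovers known delays and respects the shift bound", {
  # smooth, slowly varying signal so the SNR objective has a clean gradient
  # in the shift
  t <- (0:2999) / 1000
  y <- sin(2 * pi * t / 0.8) + 0.4 * sin(2 * pi * t / 2.7)
  # reconstruction delayed by 40 ms: y_hat[i] = y[i - 40]
  y_hat <- c(rep(0, 40), y[1:(3000 - 40)])
  al <- align_signals(y, y_hat, max_shift_ms = 100, rate = 1000)
  expect_equal(al$shift_ms, 40)
  expect_equal(snr(al$y, al$y_hat), Inf)

  # true delay beyond the bound: chosen shift saturates at 100 ms
  y_hat2 <- c(rep(0, 150), y[1:(3000 - 150)])
  al2 <- align_signals(y, y_hat2, max_shift_ms = 100, rate = 1000)
  expect_equal(al2$shift_ms, 100)
})

test_that("the selected shift equals exhaustive enumeration", {
  set.seed(2)
  for (rep in 1:20) {
    y <- cumsum(rnorm(600))
    y_hat <- c(rep(0, rep %% 7), y[1:(600 - rep %% 7)]) + rnorm(600, 0, 0.2)
    al <- align_signals(y, y_hat, max_shift_ms = 25, rate = 1000)
    # independent exhaustive search
    best <- -Inf; best_k <- NA
    for (k in -25:25) {
      i0 <- max(1, 1 - k); i1 <- min(600, 600 - k)
      yc <- y[i0:i1] - mean(y[i0:i1])
      hc <- y_hat[(i0 + k):(i1 + k)]
      hc <- hc - mean(hc)
      q <- sum(yc^2) / sum((yc - hc)^2)
      if (q > best) {
        best <- q; best_k <- k
      }
    }
    expect_equal(al$shift_ms, best_k, label = sprintf("rep %d", rep))
  }
})

test_that("SNR follows its closed forms and sentinels", {
  set.seed(3)
  y <- rnorm(1000)
  y <- y - mean(y)
  expect_equal(snr(y, rep(0, 1000)), 0) # all-zero reconstruction: 0 dB
  expect_equal(snr(y, y), Inf)
  expect_equal(snr(y, 0.9 * y), 20, tolerance = 1e-9)
  expect_warning(s <- snr(rep(0, 10), rnorm(10)), "zero signal power")
  expect_true(is.nan(s))
  # invariance to constant offsets happens through centering in alignment
  # (floating-point mean subtraction leaves only a negligible residual)
  al <- align_signals(y, y + 5, max_shift_ms = 10, rate = 1000)
  expect_gt(snr(al$y, al$y_hat), 200)
})

test_that("RMSE and correlation match hand computations", {
  y <- c(0, 1, 0, -1)
  expect_equal(rmse(y, rep(0, 4)), sqrt(0.5) * 1000, tolerance = 1e-9)
  expect_equal(rmse(y, y), 0)
  expect_equal(trace_correlation(y, y), 1)
  expect_equal(trace_correlation(y, -y), -1)
  expect_warning(r <- trace_correlation(y, rep(0, 4)), "constant")
  expect_true(is.na(r))
})

test_that("SNR decreases monotonically along a noise ladder", {
  set.seed(4)
  y <- sin(2 * pi * (0:1999) / 200)
  snrs <- vapply(c(0.01, 0.05, 0.1, 0.3), function(s) {
    snr(y - mean(y), y - mean(y) + rnorm(2000, 0, s))
  }, 0)
  expect_true(all(diff(snrs) < 0))
})

test_that("the RMSE-SNR power identity holds on centred aligned pairs", {
  set.seed(5)
  y <- rnorm(1500)
  y <- y - mean(y)
  y_hat <- y + rnorm(1500, 0, 0.3)
  y_hat <- y_hat - mean(y_hat)
  s <- snr(y, y_hat)
  r <- rmse(y, y_hat) / 1000
  expect_equal(r^2, mean(y^2) * 10^(-s / 10), tolerance = 1e-9)
})

test_that("record evaluation aggregates per-lead metrics", {
  set.seed(6)
  m <- matrix(rnorm(3000 * 3), 3000, 3, dimnames = list(NULL, c("I", "II", "V1")))
  m <- scale(m, scale = FALSE)
  truth <- structure(list(leads = colnames(m), samples = m, rate = 1000,
                          duration_s = 3, calibration = NULL,
                          layout_name = NA, warnings = character()),
                     class = "ecg_record")
  recm <- m + matrix(rnorm(9000, 0, 0.2), 3000, 3)
  rec <- truth
  rec$samples <- recm
  ev <- evaluate_record(truth, rec)
  expect_equal(nrow(ev$per_lead), 3)
  # independent aggregation
  expect_equal(ev$aggregate$mean[1], mean(ev$per_lead$snr_db))
  expect_equal(ev$aggregate$sd[2], sd(ev$per_lead$rmse_uV))
  # identical records: all-sentinel SNR, zero RMSE
  ev2 <- evaluate_record(truth, truth)
  expect_true(all(ev2$per_lead$snr_db == Inf))
  expect_true(all(ev2$per_lead$rmse_uV == 0))
  expect_equal(ev2$n_inf_snr, 3)
  expect_error(evaluate_record(truth, list(samples = matrix(0, 10, 1,
    dimnames = list(NULL, "X")), rate = 1000)), "shared leads")
})

test_that("strict NaN mode excludes missing samples from the sums", {
  set.seed(7)
  y <- sin(2 * pi * (0:999) / 100)
  y_hat <- y
  y_hat[100:200] <- NA
  al_zero <- align_signals(y, y_hat, 10, 1000, nan_mode = "zero")
  al_strict <- align_signals(y, y_hat, 10, 1000, nan_mode = "strict")
  expect_lt(snr(al_zero$y, al_zero$y_hat), 20) # zeros count as noise
  expect_equal(al_strict$nan_frac, al_zero$nan_frac)
  # strict mode sees a near-perfect signal on the finite part (up to the
  # centering offset between full and finite-sample means)
  fin <- is.finite(al_strict$y_hat)
  expect_gt(snr(al_strict$y[fin], al_strict$y_hat[fin]), 40)
})
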