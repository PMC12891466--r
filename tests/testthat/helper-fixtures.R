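# Shared fixtures and independent oracles. Expensive artifacts (renders,
# trained tiny models, the homography-recovery study) are memoized in this
# environment so several test files can share one computation.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, force(expr), .fixtures)
  get(key, .fixtures)
}

one_hot_probs <- function(class_mask, n_classes = 4) {
  probs <- array(0, c(dim(class_mask), n_classes))
  for (k in seq_len(n_classes) - 1L) probs[, , k + 1] <- (class_mask == k) * 1.0
  probs
}

one_hot_text <- function(lead_text_mask) {
  probs <- array(0, c(dim(lead_text_mask), 13))
  for (k in 0:12) probs[, , k + 1] <- (lead_text_mask == k) * 1.0
  probs
}

# small clean render shared across tests (25 mm/s, ~3.9 px/mm)
fix_render <- function() {
  memo("render_small", {
    sig <- simulate_ecg(12, 10, 250, seed = 3)
    render_paper(sig, render_config(dpi = 100, speed_mm_per_s = 25, seed = 3))
  })
}

# synthetic pure-grid probability map with (possibly fractional) spacing d:
# soft line profiles centred at multiples of d, major lines every 5d heavier
synth_grid_map <- function(d, h, w, line_sd = 0.5) {
  line_profile <- function(n) {
    x <- seq_len(n) - 1
    p <- numeric(n)
    for (k in 0:floor((n - 1) / d)) {
      mu <- k * d
      wgt <- if (k %% 5 == 0) 1 else 0.7
      lo <- max(1, floor(mu - 3)); hi <- min(n, ceiling(mu + 3) + 1)
      idx <- lo:hi
      p[idx] <- pmax(p[idx], wgt * exp(-((x[idx] - mu)^2) / (2 * line_sd^2)))
    }
    p
  }
  pr <- line_profile(h); pc <- line_profile(w)
  pmin(outer(pr, pc, pmax), 1)
}

# --- independent oracles ----------------------------------------------------

# brute-force Hough voting (per pixel, per angle, straight from the line
# equation; duplicates the bin-splitting contract independently)
oracle_hough <- function(map, thetas, rho_min, rho_step, n_rho) {
  acc <- matrix(0, length(thetas), n_rho)
  for (x in seq_len(ncol(map)) - 1L) {
    for (y in seq_len(nrow(map)) - 1L) {
      v <- map[y + 1, x + 1]
      if (v <= 0) next
      for (t in seq_along(thetas)) {
        rho <- x * cos(thetas[t]) + y * sin(thetas[t])
        f <- (rho - rho_min) / rho_step
        i0 <- floor(f)
        w1 <- f - i0
        if (i0 >= 0 && i0 < n_rho) acc[t, i0 + 1] <- acc[t, i0 + 1] + v * (1 - w1)
        if (i0 + 1 >= 0 && i0 + 1 < n_rho) acc[t, i0 + 2] <- acc[t, i0 + 2] + v * w1
      }
    }
  }
  acc
}

# O(n^2) autocorrelation oracle
oracle_autocorr <- function(x, m_max) {
  vapply(0:m_max, function(m) {
    s <- 0
    for (i in seq_len(length(x) - m)) s <- s + x[i] * x[i + m]
    s
  }, 0)
}

# queue flood fill, 8-connected, independent of the Rcpp labelling
oracle_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j] || lab[i, j]) next
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni < 1 || ni > h || nj < 1 || nj > w) next
          if (mask[ni, nj] && !lab[ni, nj]) {
            lab[ni, nj] <- cur
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# exhaustive assignment minimum over all permutations (n <= 7)
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

# random homography jittering the corners of a (w x h) box
random_homography <- function(w, h, tilt_deg, seed) {
  set.seed(seed)
  s <- tan(tilt_deg * pi / 180) * min(h, w) / 2
  src <- rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1), c(0, h - 1))
  dst <- src + matrix(runif(8, -s, s), 4, 2)
  dst[, 1] <- dst[, 1] - min(dst[, 1])
  dst[, 2] <- dst[, 2] - min(dst[, 2])
  ecgdigitizer:::fit_homography4(src, dst)
}

# gridline angular deviation from the axes after rectifying a warped grid
# map; returns the max deviation (degrees) over the two recovered families
rectification_deviation <- function(seed, tilt_deg = 15, h = 260, w = 420,
                                    d = 5) {
  gm <- synth_grid_map(d, h, w)
  hm <- random_homography(w, h, tilt_deg, seed)
  corners <- apply_homography(hm, rbind(c(0, 0), c(w - 1, 0),
                                        c(w - 1, h - 1), c(0, h - 1)))
  out_w <- ceiling(max(corners[, 1])) + 1
  out_h <- ceiling(max(corners[, 2])) + 1
  gmw <- ecgdigitizer:::warp_image(gm, hm, out_h, out_w, "bilinear")
  fams <- find_line_families(gmw)
  stack <- array(0, c(out_h, out_w, 4))
  stack[, , 2] <- gmw
  stack[, , 3] <- gmw # stand-in so the crop keeps the grid
  dw <- rectify(array(0.5, c(out_h, out_w, 3)), stack, fams,
                equalize_axes = FALSE)
  f2 <- find_line_families(dw$probs[, , 2])
  devs <- vapply(f2, function(f) {
    a <- c(f$theta_rho_min, f$theta_rho_max) * 180 / pi
    max(abs(((a + 45) %% 90) - 45))
  }, 0)
  max(devs)
}

homography_recovery_study <- function(n = 50) {
  memo(paste0("homog_study_", n), {
    vapply(seq_len(n), function(s) rectification_deviation(seed = 1000 + s), 0)
  })
}

# jittered synthetic marker set for a layout template (drop_n markers
# removed, positions perturbed by `jitter` of the image size)
make_marker_set <- function(template, jitter, drop_n, seed, w = 1000,
                            h = 700) {
  set.seed(seed)
  g <- generate_layout(template)
  x <- (0.12 + 0.75 * g$x) * w + rnorm(nrow(g), 0, jitter * w)
  y <- (0.08 + 0.84 * g$y) * h + rnorm(nrow(g), 0, jitter * h)
  keep <- seq_len(nrow(g))
  if (drop_n > 0) keep <- sort(sample(keep, nrow(g) - drop_n))
  df <- data.frame(lead = g$lead[keep], x = x[keep], y = y[keep],
                   mass = 50, stringsAsFactors = FALSE)
  structure(df, width = w, height = h, class = c("marker_set", "data.frame"))
}

# --- shared tiny models -----------------------------------------------------

tiny_unet_config <- function(out_channels = 4, in_channels = 3) {
  unet_config(c(8, 16, 32), in_channels = in_channels,
              out_channels = out_channels)
}

# one fixed batch of crops from the shared render (for the overfit check);
# crops must contain every class with a useful number of pixels, or the
# batch cannot demonstrate foreground learning at all
fix_overfit_batch <- function(n = 2, size = 64) {
  memo("overfit_batch", {
    rs <- fix_render()
    out <- list()
    seed <- 0
    while (length(out) < n && seed < 500) {
      seed <- seed + 1
      cr <- make_training_crop(rs, size, seed = seed)
      counts <- tabulate(cr$class_mask + 1L, nbins = 4)
      if (all(counts >= 30)) out[[length(out) + 1]] <- cr
    }
    stopifnot(length(out) == n)
    out
  })
}

fix_overfit_model <- function() {
  memo("overfit_model", {
    batch <- fix_overfit_batch()
    model <- build_main_unet(tiny_unet_config(), seed = 5)
    cfg <- train_config(batch_size = length(batch), patch_px = 64,
                        schedule_batches = 200, seed = 5)
    train_unet(model, function(step) batch, cfg, n_steps = 200)
  })
}

foreground_dice <- function(model, batch) {
  scores <- vapply(batch, function(s) {
    probs <- softmax_hwc_test(unet_forward(model, s$image)$logits)
    pred <- apply(probs, c(1, 2), which.max) - 1L
    truth <- s$class_mask
    fg <- truth > 0 | pred > 0
    dices <- vapply(1:3, function(k) {
      a <- pred == k; b <- truth == k
      if (!any(b) && !any(a)) return(NA_real_)
      2 * sum(a & b) / (sum(a) + sum(b))
    }, 0)
    mean(dices, na.rm = TRUE)
  }, 0)
  mean(scores)
}

softmax_hwc_test <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  xm <- xm - apply(xm, 1, max)
  e <- exp(xm)
  array(e / rowSums(e), d)
}

# tiny main model trained on varied crops (for the end-to-end check)
fix_e2e_main_model <- function() {
  memo("e2e_main_model", {
    rs <- fix_render()
    model <- build_main_unet(unet_config(c(12, 24, 48)), seed = 11)
    stream <- function(step) {
      lapply(1:2, function(i) make_training_crop(rs, 64, seed = step * 10 + i))
    }
    cfg <- train_config(batch_size = 2, patch_px = 64,
                        schedule_batches = 600, seed = 11)
    train_unet(model, stream, cfg, n_steps = 600)
  })
}

# oracle-mask round trip on a clean 50 mm/s scan, memoized
fix_oracle_roundtrip <- function() {
  memo("oracle_roundtrip", {
    sig <- simulate_ecg(12, 10, 500, seed = 7)
    rs <- render_paper(sig, render_config(dpi = 254, speed_mm_per_s = 50,
                                          seed = 7))
    probs <- ground_truth_probs(rs)
    tprobs <- ground_truth_text_probs(rs)
    cfg <- pipeline_config(speed_mm_per_s = 50, gain_mm_per_mV = 10)
    rec <- digitize_from_maps(probs, cfg, image = rs$image,
                              text_probs = tprobs)
    truth <- signal_to_record(simulate_ecg(12, 10, 1000, seed = 7))
    list(record = rec,
         eval = evaluate_record(truth, rec, span = "observed"),
         render = rs)
  })
}
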