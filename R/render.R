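#' Rendering configuration for synthetic paper ECGs
#'
#' @param speed_mm_per_s Paper speed in mm/s (25 or 50 are the clinical
#'   standards; any positive value is accepted).
#' @param gain_mm_per_mV Vertical scale in mm/mV (default 10).
#' @param dpi Render resolution in dots per inch; pixels per mm is
#'   `dpi / 25.4`.
#' @param layout_name Registered layout template id (see [load_layouts()]).
#' @param line_width_px Width of the drawn ECG trace in pixels; `NULL`
#'   (default) picks a 0.2 mm pen at the render resolution.
#' @param line_color RGB triplet of the trace color.
#' @param grid_color RGB triplet of the minor grid line color; major lines
#'   are drawn 25 percent darker.
#' @param background_style Paper fill: `"white"` or `"cream"`.
#' @param text_font_scale Integer font scale (pixels per font unit); `NULL`
#'   picks a size of about 3 mm.
#' @param row_mm Vertical strip height per lead row, in mm.
#' @param margin_mm Paper margin around the plotted area, in mm.
#' @param seed Integer seed for any randomized rendering choices.
#' @return A `render_config` list.
#' @export
render_config <- function(speed_mm_per_s = 25, gain_mm_per_mV = 10, dpi = 100,
                          layout_name = "3x4+II", line_width_px = NULL,
                          line_color = c(0, 0, 0),
                          grid_color = c(1, 0.6, 0.6),
                          background_style = "white", text_font_scale = NULL,
                          row_mm = 30, margin_mm = 10, seed = 1) {
  if (speed_mm_per_s <= 0 || gain_mm_per_mV <= 0) stop("speed and gain must be > 0")
  if (dpi <= 0) stop("dpi must be > 0")
  structure(list(speed_mm_per_s = speed_mm_per_s,
                 gain_mm_per_mV = gain_mm_per_mV, dpi = dpi,
                 layout_name = layout_name, line_width_px = line_width_px,
                 line_color = line_color, grid_color = grid_color,
                 background_style = background_style,
                 text_font_scale = text_font_scale, row_mm = row_mm,
                 margin_mm = margin_mm, seed = seed),
            class = "render_config")
}

# segmentation class codes
CLASS_BG <- 0L; CLASS_GRID <- 1L; CLASS_SIGNAL <- 2L; CLASS_TEXT <- 3L

#' Render a multi-lead signal as a synthetic paper ECG
#'
#' Draws standard ECG paper (minor grid lines every 1 mm, major lines every
#' 5 mm), places each lead's time window into its layout panel at the
#' configured speed/gain scaling, and prints the lead name near the top-left
#' corner of each panel using a built-in bitmap font. Pixel-accurate class
#' masks are produced alongside the image.
#'
#' @param signal A `multi_lead_signal` covering every lead and time window of
#'   the layout.
#' @param config A [render_config()].
#' @param layouts Optional layout registry (defaults to the bundled one).
#' @return A `rendered_sample`: list with `image` (H x W x 3), `class_mask`
#'   (H x W integer, 0 = background, 1 = grid, 2 = signal, 3 = text),
#'   `lead_text_mask` (0 = background, 1..12 = lead index in the standard
#'   order), `truth` (the input signal plus the panel table in pixel
#'   coordinates), `homography` (identity), `calibration_truth` (pixels per
#'   mm) and the `layout` template used.
#' @export
render_paper <- function(signal, config = render_config(), layouts = NULL) {
  template <- resolve_template(config$layout_name, layouts)
  needed <- unique(template$panels$lead)
  if (!all(needed %in% signal$lead_names)) {
    stop("signal is missing leads required by the layout: ",
         paste(setdiff(needed, signal$lead_names), collapse = ", "))
  }
  dur <- nrow(signal$samples) / signal$rate
  if (dur + 1e-9 < template$duration_s) {
    stop("signal shorter than the layout window (", template$duration_s, " s)")
  }
  ppm <- config$dpi / 25.4
  n_strips <- max(template$panels$row)
  plot_w_mm <- template$duration_s * config$speed_mm_per_s
  plot_h_mm <- n_strips * config$row_mm
  w <- round((plot_w_mm + 2 * config$margin_mm) * ppm)
  h <- round((plot_h_mm + 2 * config$margin_mm) * ppm)
  x0 <- config$margin_mm * ppm # left edge of plot area (0-based px)
  y0 <- config$margin_mm * ppm

  paper_col <- if (identical(config$background_style, "cream")) {
    c(1, 0.99, 0.94)
  } else {
    c(1, 1, 1)
  }
  img <- array(rep(paper_col, each = h * w), c(h, w, 3))
  class_mask <- matrix(CLASS_BG, h, w)
  text_mask <- matrix(0L, h, w)

  # --- grid over the whole paper ------------------------------------------
  expand_px <- function(centers, width, limit) {
    lo <- floor((width - 1) / 2); hi <- ceiling((width - 1) / 2)
    px <- unique(as.vector(outer(centers, (-lo):hi, `+`)))
    px[px >= 1 & px <= limit]
  }
  minor_cols <- unique(round(seq(0, (w - 1) / ppm) * ppm)) + 1L
  minor_rows <- unique(round(seq(0, (h - 1) / ppm) * ppm)) + 1L
  minor_cols <- minor_cols[minor_cols >= 1 & minor_cols <= w]
  minor_rows <- minor_rows[minor_rows >= 1 & minor_rows <= h]
  # minor rulings ~0.1 mm, major rulings ~0.25 mm
  w_minor <- max(1L, round(0.10 * ppm))
  w_major <- max(1L, round(0.25 * ppm))
  major_col_px <- expand_px(minor_cols[(seq_along(minor_cols) - 1) %% 5 == 0], w_major, w)
  major_row_px <- expand_px(minor_rows[(seq_along(minor_rows) - 1) %% 5 == 0], w_major, h)
  minor_col_px <- expand_px(minor_cols, w_minor, w)
  minor_row_px <- expand_px(minor_rows, w_minor, h)
  gcol <- config$grid_color
  gmaj <- config$grid_color * 0.75
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[, minor_col_px] <- gcol[ch]
    plane[minor_row_px, ] <- gcol[ch]
    plane[, major_col_px] <- gmaj[ch]
    plane[major_row_px, ] <- gmaj[ch]
    img[, , ch] <- plane
  }
  class_mask[, minor_col_px] <- CLASS_GRID
  class_mask[minor_row_px, ] <- CLASS_GRID
  class_mask[, major_col_px] <- CLASS_GRID
  class_mask[major_row_px, ] <- CLASS_GRID

  # --- panels: pixel-space geometry ---------------------------------------
  p <- template$panels
  panels <- data.frame(
    lead = p$lead, rhythm = p$rhythm, t0 = p$t0, t1 = p$t1,
    c0 = round(x0 + p$x0 * plot_w_mm * ppm),
    c1 = round(x0 + p$x1 * plot_w_mm * ppm),
    r0 = round(y0 + (p$row - 1) * config$row_mm * ppm),
    r1 = round(y0 + p$row * config$row_mm * ppm),
    stringsAsFactors = FALSE
  )
  panels$baseline_row <- (panels$r0 + panels$r1) / 2

  # --- lead name labels ----------------------------------------------------
  fscale <- config$text_font_scale %||% max(1L, round(0.4 * ppm))
  for (i in seq_len(nrow(panels))) {
    glyph <- render_label(panels$lead[i], fscale)
    rr <- panels$r0[i] + round(0.06 * (panels$r1[i] - panels$r0[i]))
    cc <- panels$c0[i] + round(0.02 * (panels$c1[i] - panels$c0[i])) + 2L
    ri <- rr + seq_len(nrow(glyph)); ci <- cc + seq_len(ncol(glyph))
    keep_r <- ri >= 1 & ri <= h; keep_c <- ci >= 1 & ci <= w
    g <- glyph[keep_r, keep_c, drop = FALSE]
    ri <- ri[keep_r]; ci <- ci[keep_c]
    sub <- class_mask[ri, ci, drop = FALSE]
    sub[g == 1L] <- CLASS_TEXT
    class_mask[ri, ci] <- sub
    subt <- text_mask[ri, ci, drop = FALSE]
    subt[g == 1L] <- match(panels$lead[i], LEAD_NAMES)
    text_mask[ri, ci] <- subt
    for (ch in 1:3) {
      plane <- img[ri, ci, ch]
      plane[g == 1L] <- config$line_color[ch]
      img[ri, ci, ch] <- plane
    }
  }

  # --- traces --------------------------------------------------------------
  # alongside the binary mask, a subpixel coverage plane records, for each
  # pixel, the fraction covered by the (continuous) ink band; it serves as
  # pixel-accurate soft ground truth for the signal class
  tgrid <- (seq_len(nrow(signal$samples)) - 1) / signal$rate
  sig_mask <- matrix(FALSE, h, w)
  sig_soft <- matrix(0, h, w)
  lw <- max(1L, as.integer(config$line_width_px %||% round(0.2 * ppm)))
  for (i in seq_len(nrow(panels))) {
    v <- signal$samples[, panels$lead[i]]
    cols <- seq(panels$c0[i], panels$c1[i] - 1L)
    tt <- panels$t0[i] + (cols - panels$c0[i]) / (ppm * config$speed_mm_per_s)
    tt <- pmin(tt, panels$t1[i] - 1e-9)
    vv <- approx(tgrid, v, xout = tt, rule = 2)$y
    ycont <- panels$baseline_row[i] - vv * config$gain_mm_per_mV * ppm
    ycont <- clamp(ycont, 1, h)
    rows <- round(ycont)
    for (k in seq_along(cols)) {
      span <- if (k == 1) rows[k]:rows[k] else {
        a <- rows[k - 1]; b <- rows[k]
        if (a == b) b:b else (a + sign(b - a)):b
      }
      sig_mask[span, cols[k]] <- TRUE
      seg_lo <- (if (k == 1) ycont[k] else min(ycont[k - 1], ycont[k])) - lw / 2
      seg_hi <- (if (k == 1) ycont[k] else max(ycont[k - 1], ycont[k])) + lw / 2
      r_lo <- max(1L, floor(seg_lo)); r_hi <- min(h, ceiling(seg_hi))
      rr <- r_lo:r_hi
      cov <- pmin(rr + 0.5, seg_hi) - pmax(rr - 0.5, seg_lo)
      cov <- pmin(1, pmax(0, cov))
      sig_soft[rr, cols[k]] <- pmax(sig_soft[rr, cols[k]], cov)
    }
  }
  if (lw > 1L) sig_mask <- dilate_mask(sig_mask, lw)
  class_mask[sig_mask] <- CLASS_SIGNAL
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[sig_mask] <- config$line_color[ch]
    img[, , ch] <- plane
  }

  structure(list(image = img, class_mask = class_mask,
                 signal_soft = sig_soft,
                 lead_text_mask = text_mask,
                 truth = list(signal = signal, panels = panels),
                 homography = diag(3), calibration_truth = ppm,
                 layout = template, config = config,
                 paper_corners = rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1),
                                       c(0, h - 1))),
            class = "rendered_sample")
}

# binary dilation with a centred square structuring element of width `k`
dilate_mask <- function(mask, k) {
  r <- (k - 1L) %/% 2L
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (dy in -r:(k - 1L - r)) {
    for (dx in -r:(k - 1L - r)) {
      if (dy == 0 && dx == 0) next
      src_r <- max(1, 1 - dy):min(h, h - dy)
      src_c <- max(1, 1 - dx):min(w, w - dx)
      out[src_r + dy, src_c + dx] <- out[src_r + dy, src_c + dx] | mask[src_r, src_c]
    }
  }
  out
}

#' Ground-truth class probability maps of a rendered sample
#'
#' Builds the H x W x 4 probability array (background, grid, signal, text)
#' a perfect segmentation network would produce. With `soft_signal = TRUE`
#' (default) the signal class uses the renderer's subpixel coverage plane,
#' enabling sub-quantization trace recovery; otherwise all classes are
#' one-hot from the class mask.
#'
#' @param sample A `rendered_sample`.
#' @param soft_signal Use the subpixel signal coverage plane.
#' @return H x W x 4 probability array.
#' @export
ground_truth_probs <- function(sample, soft_signal = TRUE) {
  m <- sample$class_mask
  probs <- array(0, c(dim(m), 4))
  if (soft_signal && !is.null(sample$signal_soft)) {
    sig <- pmax(sample$signal_soft, (m == CLASS_SIGNAL) * 0.51)
    probs[, , 3] <- sig
    probs[, , 2] <- (m == CLASS_GRID) * (1 - sig)
    probs[, , 4] <- (m == CLASS_TEXT) * (1 - sig)
    probs[, , 1] <- pmax(0, 1 - probs[, , 2] - sig - probs[, , 4])
  } else {
    for (k in 0:3) probs[, , k + 1] <- (m == k) * 1.0
  }
  probs
}

#' Ground-truth lead-text probability maps of a rendered sample
#'
#' @param sample A `rendered_sample`.
#' @return H x W x 13 one-hot probability array (background + 12 leads).
#' @export
ground_truth_text_probs <- function(sample) {
  m <- sample$lead_text_mask
  probs <- array(0, c(dim(m), 13))
  for (k in 0:12) probs[, , k + 1] <- (m == k) * 1.0
  probs
}

#' @export
print.rendered_sample <- function(x, ...) {
  cat(sprintf("<rendered_sample> %d x %d px, layout %s, %.3f px/mm\n",
              dim(x$image)[1], dim(x$image)[2], x$layout$name,
              x$calibration_truth))
  invisible(x)
}

#' Apply a random perspective warp and composite a background
#'
#' Warps the image and all masks by the same random homography (recorded in
#' the returned sample) and fills the area outside the paper with a
#' procedurally generated background. With `max_tilt_deg = 0` the homography
#' is the identity and the sample is returned with (at most) a canvas margin.
#'
#' @param sample A `rendered_sample`.
#' @param max_tilt_deg Maximum corner displacement expressed as a tilt angle;
#'   0 disables warping.
#' @param background_style `"gradient"`, `"noise"` or `"table"`.
#' @param seed Integer seed.
#' @return A `rendered_sample` with updated image, masks, `homography` and
#'   `paper_corners`.
#' @export
apply_perspective <- function(sample, max_tilt_deg = 10,
                              background_style = "gradient", seed = 1) {
  if (max_tilt_deg < 0) stop("max_tilt_deg must be >= 0")
  if (max_tilt_deg == 0) return(sample)
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  s <- tan(max_tilt_deg * pi / 180) * min(h, w) / 2
  for (attempt in 1:20) {
    src <- rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1), c(0, h - 1))
    dst <- src + matrix(runif(8, -s, s), 4, 2)
    dst[, 1] <- dst[, 1] - min(dst[, 1])
    dst[, 2] <- dst[, 2] - min(dst[, 2])
    hm <- tryCatch(fit_homography4(src, dst), error = function(e) NULL)
    if (!is.null(hm) && abs(det(hm)) > 1e-8) break
    hm <- NULL
  }
  if (is.null(hm)) stop("could not sample an invertible homography")
  out_w <- ceiling(max(dst[, 1])) + 1L
  out_h <- ceiling(max(dst[, 2])) + 1L
  img <- warp_image(sample$image, hm, out_h, out_w, "bilinear", fill = 0)
  cmask <- warp_image(sample$class_mask + 0, hm, out_h, out_w, "nearest", fill = 0)
  tmask <- warp_image(sample$lead_text_mask + 0, hm, out_h, out_w, "nearest", fill = 0)
  inside <- warp_image(matrix(1, h, w), hm, out_h, out_w, "nearest", fill = 0)
  bg <- make_background(out_h, out_w, background_style)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside == 0] <- bg[, , ch][inside == 0]
    img[, , ch] <- plane
  }
  sample$image <- img
  sample$class_mask <- matrix(as.integer(round(cmask)), out_h, out_w)
  sample$lead_text_mask <- matrix(as.integer(round(tmask)), out_h, out_w)
  sample$homography <- hm %*% sample$homography
  sample$paper_corners <- apply_homography(hm, sample$paper_corners)
  if (!is.null(sample$truth$panels)) {
    sample$truth$warped <- TRUE
  }
  sample
}

make_background <- function(h, w, style = c("gradient", "noise", "table")) {
  style <- match.arg(style)
  xs <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
  ys <- matrix(rep(seq(0, 1, length.out = h), w), h, w)
  if (style == "gradient") {
    c1 <- runif(3, 0.1, 0.9); c2 <- runif(3, 0.1, 0.9)
    ang <- runif(1, 0, 2 * pi)
    tmix <- (xs * cos(ang) + ys * sin(ang) + 1) / 2
    out <- array(0, c(h, w, 3))
    for (ch in 1:3) out[, , ch] <- c1[ch] * (1 - tmix) + c2[ch] * tmix
  } else if (style == "noise") {
    lo_h <- max(2L, h %/% 32L); lo_w <- max(2L, w %/% 32L)
    out <- array(0, c(h, w, 3))
    base <- runif(3, 0.2, 0.8)
    for (ch in 1:3) {
      lo <- matrix(runif(lo_h * lo_w, -0.2, 0.2), lo_h, lo_w)
      out[, , ch] <- clamp(base[ch] + resize_bilinear(lo, h, w), 0, 1)
    }
  } else {
    base <- c(runif(1, 0.35, 0.55), runif(1, 0.2, 0.35), runif(1, 0.08, 0.2))
    stripe <- 0.06 * sin(2 * pi * ys * runif(1, 4, 9) + runif(1, 0, 2 * pi))
    out <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      out[, , ch] <- clamp(base[ch] + stripe + rnorm(h * w, 0, 0.01), 0, 1)
    }
  }
  out
}

# bilinear resize of a matrix to (h, w)
resize_bilinear <- function(m, h, w) {
  sy <- (seq_len(h) - 0.5) / h * nrow(m) + 0.5
  sx <- (seq_len(w) - 0.5) / w * ncol(m) + 0.5
  y0 <- clamp(floor(sy), 1, nrow(m)); y1 <- clamp(y0 + 1, 1, nrow(m))
  x0 <- clamp(floor(sx), 1, ncol(m)); x1 <- clamp(x0 + 1, 1, ncol(m))
  fy <- clamp(sy - y0, 0, 1); fx <- clamp(sx - x0, 0, 1)
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  fym <- matrix(fy, h, w); fxm <- matrix(fx, h, w, byrow = TRUE)
  m00 * (1 - fym) * (1 - fxm) + m01 * (1 - fym) * fxm +
    m10 * fym * (1 - fxm) + m11 * fym * fxm
}

#' Apply a smooth brightness field emulating thermal-paper fading
#'
#' @param sample A `rendered_sample`.
#' @param strength Maximum relative darkening in \[0, 1\].
#' @param seed Integer seed.
#' @return The sample with a modulated image (masks unchanged).
#' @export
apply_fading <- function(sample, strength = 0.15, seed = 1) {
  if (strength <= 0) return(sample)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  lo <- matrix(runif(48, 1 - strength, 1), 6, 8)
  field <- resize_bilinear(lo, h, w)
  for (ch in 1:3) sample$image[, , ch] <- sample$image[, , ch] * field
  sample
}

#' Extract an aligned training crop from a rendered sample
#'
#' @param sample A `rendered_sample`.
#' @param size_px Square crop size. Samples smaller than the crop are padded
#'   with white background (class label background).
#' @param seed Integer seed for the crop position.
#' @return List with `image` (size x size x 3) and `class_mask`
#'   (size x size integer).
#' @export
make_training_crop <- function(sample, size_px, seed = 1) {
  h <- dim(sample$image)[1]; w <- dim(sample$image)[2]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  img <- sample$image
  mask <- sample$class_mask
  if (h < size_px || w < size_px) {
    ph <- max(h, size_px); pw <- max(w, size_px)
    big <- array(1, c(ph, pw, 3))
    big[seq_len(h), seq_len(w), ] <- img
    bm <- matrix(CLASS_BG, ph, pw)
    bm[seq_len(h), seq_len(w)] <- mask
    img <- big; mask <- bm; h <- ph; w <- pw
  }
  r0 <- sample.int(h - size_px + 1L, 1L)
  c0 <- sample.int(w - size_px + 1L, 1L)
  list(image = img[r0:(r0 + size_px - 1L), c0:(c0 + size_px - 1L), , drop = FALSE],
       class_mask = mask[r0:(r0 + size_px - 1L), c0:(c0 + size_px - 1L)])
}
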