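#' Pipeline configuration
#'
#' @param main_model `unet_model` for the 4-class segmentation (or a path to
#'   a checkpoint saved with [save_checkpoint()]).
#' @param text_model Optional `unet_model` for the 13-class lead-text
#'   segmentation (or a checkpoint path).
#' @param layouts Layout registry (list of `layout_template`s) or a path to
#'   a YAML layout config; defaults to the bundled registry.
#' @param speed_mm_per_s,gain_mm_per_mV Paper constants (defaults 25, 10).
#' @param target_rate Output sample rate in Hz (default 1000).
#' @param default_layout Template used when layout identification fails.
#' @param min_markers Minimum number of detected lead markers required to
#'   trust layout matching; with fewer, the default layout is used
#'   (a per-axis transform fitted on almost no points is meaningless).
#' @param min_signal_px Minimum number of super-threshold signal pixels for
#'   the image to be treated as containing a recording at all (default
#'   500); below it the record is all-NA with a warning. Any legible paper
#'   ECG has orders of magnitude more trace pixels.
#' @param signal_threshold Signal-probability threshold for tracing.
#' @param min_component_mass Speck rejection threshold (probability mass).
#' @param max_snip_iter Snip-merge iteration budget.
#' @param tile_px,overlap_px Tiled-inference geometry for [segment()].
#' @param map_interp Probability-map interpolation during rectification:
#'   `"bilinear"` for soft network outputs (default), `"nearest"` for crisp
#'   label-derived maps.
#' @param debug_dir Optional directory for per-stage debug artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(main_model = NULL, text_model = NULL,
                            layouts = NULL, speed_mm_per_s = 25,
                            gain_mm_per_mV = 10, target_rate = 1000,
                            default_layout = "3x4+II", min_markers = 4,
                            min_signal_px = 500,
                            signal_threshold = 0.5, min_component_mass = 10,
                            max_snip_iter = 10, tile_px = 1024,
                            overlap_px = 128, map_interp = "bilinear",
                            debug_dir = NULL) {
  if (is.character(main_model)) {
    if (!file.exists(main_model)) stop("model checkpoint not found: ", main_model)
    main_model <- load_checkpoint(main_model)
  }
  if (is.character(text_model)) {
    if (!file.exists(text_model)) stop("model checkpoint not found: ", text_model)
    text_model <- load_checkpoint(text_model)
  }
  if (is.character(layouts)) layouts <- load_layouts(layouts)
  if (target_rate <= 0) stop("target_rate must be > 0")
  structure(list(main_model = main_model, text_model = text_model,
                 layouts = layouts %||% load_layouts(),
                 speed_mm_per_s = speed_mm_per_s,
                 gain_mm_per_mV = gain_mm_per_mV, target_rate = target_rate,
                 default_layout = default_layout, min_markers = min_markers,
                 min_signal_px = min_signal_px,
                 signal_threshold = signal_threshold,
                 min_component_mass = min_component_mass,
                 max_snip_iter = max_snip_iter, tile_px = tile_px,
                 overlap_px = overlap_px, map_interp = map_interp,
                 debug_dir = debug_dir),
            class = "pipeline_config")
}

#' Digitize a paper ECG image into a calibrated multi-lead record
#'
#' Runs the five-stage pipeline: segmentation, perspective correction and
#' cropping, grid-spacing calibration, layout identification, and
#' segmentation-to-trace conversion. Stage failures degrade gracefully
#' (rotation-only or identity dewarp, default grid spacing, default layout,
#' NA samples) and are reported in the record's `warnings`; no image is
#' rejected.
#'
#' @param image Path to a PNG/TIFF/JPEG image, or an H x W x 3 array.
#' @param config A [pipeline_config()] with at least `main_model` set.
#' @return An `ecg_record`.
#' @export
digitize <- function(image, config) {
  if (is.null(config$main_model)) stop("pipeline config has no main model")
  if (is.character(image)) image <- read_image(image)
  probs <- segment(config$main_model, image, config$tile_px, config$overlap_px)
  digitize_from_maps(probs, config, image = image)
}

#' Digitize from precomputed probability maps
#'
#' The workhorse behind [digitize()], also usable with oracle probability
#' maps (e.g. ground-truth masks converted to one-hot probabilities) to
#' exercise the geometric stages without a segmentation network.
#'
#' @param probs H x W x 4 class-probability array (background, grid,
#'   signal, text).
#' @param config A [pipeline_config()].
#' @param image Optional underlying image (for debug output only).
#' @param text_probs Optional H x W x 13 lead-text probability array
#'   (same geometry as `probs`); when NULL the config's `text_model` is
#'   applied to the dewarped text plane.
#' @return An `ecg_record`.
#' @export
digitize_from_maps <- function(probs, config, image = NULL,
                               text_probs = NULL) {
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)
  if (is.null(image)) image <- array(0, c(dim(probs)[1:2], 3))

  # --- stage 2: perspective correction and cropping ------------------------
  dew <- tryCatch({
    fams <- find_line_families(probs[, , 2])
    rectify(image, probs, fams, map_interp = config$map_interp)
  }, dewarp_failure = function(e) {
    note(paste("dewarp failed:", conditionMessage(e), "- rotation fallback"))
    ang <- estimate_rotation(probs[, , 2])
    tryCatch(rectify_rotation(image, probs, ang,
                              map_interp = config$map_interp),
             error = function(e2) NULL)
  }, error = function(e) {
    note(paste("dewarp error:", conditionMessage(e)))
    NULL
  })
  if (is.null(dew)) {
    note("dewarp fallback failed; using the image as-is")
    dew <- list(image = image, probs = probs,
                homography = diag(3), crop = c(1, dim(probs)[1], 1, dim(probs)[2]),
                signal_bbox = c(1, dim(probs)[1], 1, dim(probs)[2]),
                had_signal = any(probs[, , 3] > 0.5))
  }
  dprobs <- dew$probs
  # lead-text probabilities travel as an argmax label plane plus a
  # confidence plane; both are warped straight into the crop
  dtext <- if (!is.null(text_probs)) {
    am <- argmax_planes(text_probs)
    list(label = round(warp_into_crop(am$which - 1, dew, "nearest")),
         conf = warp_into_crop(am$max, dew, "bilinear"))
  }

  # --- stage 3: grid-spacing calibration -----------------------------------
  bbox <- dew$signal_bbox
  calib <- tryCatch({
    ex <- estimate_spacing_from_map(dprobs[, , 2], "horizontal")
    ey <- estimate_spacing_from_map(dprobs[, , 2], "vertical")
    to_physical(ex, ey, config$speed_mm_per_s, config$gain_mm_per_mV)
  }, calibration_failure = function(e) {
    note(paste("calibration failed:", conditionMessage(e), "- default spacing"))
    NULL
  }, error = function(e) {
    note(paste("calibration error:", conditionMessage(e)))
    NULL
  })
  if (is.null(calib)) {
    # fall back to assuming the signal spans the full recording
    dflt <- resolve_template(config$default_layout, config$layouts)
    d_guess <- (bbox[4] - bbox[3] + 1) /
      (dflt$duration_s * config$speed_mm_per_s)
    if (!is.finite(d_guess) || d_guess <= 0) d_guess <- 8
    calib <- to_physical(d_guess, d_guess, config$speed_mm_per_s,
                         config$gain_mm_per_mV)
  }

  # --- stage 4: layout identification --------------------------------------
  markers <- NULL
  match <- tryCatch({
    markers <- if (!is.null(dtext)) {
      detect_markers(dtext)
    } else if (!is.null(config$text_model)) {
      detect_markers(dprobs[, , 4], config$text_model)
    }
    if (is.null(markers) || nrow(markers) < (config$min_markers %||% 4)) {
      note("too few lead markers detected; using default layout")
      structure(list(template = resolve_template(config$default_layout,
                                                 config$layouts),
                     cost = Inf, matched = NULL, transform = NULL,
                     fallback = TRUE), class = "layout_match")
    } else {
      withCallingHandlers(
        match_layout(markers, config$layouts, default = config$default_layout),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  }, error = function(e) {
    note(paste("layout identification error:", conditionMessage(e)))
    structure(list(template = resolve_template(config$default_layout,
                                               config$layouts),
                   cost = Inf, matched = NULL, transform = NULL,
                   fallback = TRUE), class = "layout_match")
  })
  template <- match$template

  # --- stage 5: segmentation-to-trace conversion ---------------------------
  smap <- dprobs[, , 3]
  h <- nrow(smap); w <- ncol(smap)
  sec_per_px <- calib$seconds_per_px
  traces <- list()
  enough_signal <- sum(smap > config$signal_threshold) >=
    (config$min_signal_px %||% 500)
  if (isTRUE(dew$had_signal %||% TRUE) && enough_signal) {
    c_left <- bbox[3]; c_right <- bbox[4]
    # vertical anchors: marker fit when available, else the signal bbox
    p <- template$panels
    n_strips <- max(p$row)
    strip_frac <- cbind((seq_len(n_strips) - 1) / n_strips,
                        seq_len(n_strips) / n_strips)
    y_of <- NULL
    if (!is.null(match$transform) && !isTRUE(match$fallback)) {
      ay <- match$transform$y[1]; by <- match$transform$y[2]
      if (is.finite(ay) && abs(ay) > 1e-9) {
        y_of <- function(yt) ((yt - by) / ay) * h
      }
    }
    if (is.null(y_of)) {
      anchor_first <- 0.5 / n_strips
      anchor_last <- (n_strips - 0.5) / n_strips
      if (n_strips > 1) {
        bbox_slope <- (bbox[2] - bbox[1]) / (anchor_last - anchor_first)
        y_of <- local({
          a0 <- anchor_first; sl <- bbox_slope; top <- bbox[1]
          function(yt) top + (yt - a0) * sl
        })
      } else {
        y_of <- local({
          top <- bbox[1]; hgt <- bbox[2] - bbox[1]
          function(yt) top + yt * hgt
        })
      }
    }
    for (si in seq_len(n_strips)) {
      r_top <- max(1, round(y_of(strip_frac[si, 1])))
      r_bot <- min(h, round(y_of(strip_frac[si, 2])))
      if (r_bot <= r_top) next
      band <- smap[r_top:r_bot, , drop = FALSE]
      chains <- tryCatch(
        band_chains(band, band_height = (r_bot - r_top + 1),
                    threshold = config$signal_threshold,
                    min_mass = config$min_component_mass,
                    max_iter = config$max_snip_iter),
        error = function(e) {
          note(sprintf("tracing failed in strip %d: %s", si,
                       conditionMessage(e)))
          list()
        })
      chain <- unlist(chains, recursive = FALSE)
      tr <- if (length(chain)) {
        suppressWarnings(chain_to_trace(chain, band, calib,
                                        col_range = c(c_left, c_right)))
      }
      strip_leads <- p[p$row == si, , drop = FALSE]
      for (li in seq_len(nrow(strip_leads))) {
        lead <- strip_leads$lead[li]
        x0 <- strip_leads$x0[li]; x1 <- strip_leads$x1[li]
        c0 <- round(c_left + x0 * (c_right - c_left))
        c1 <- round(c_left + x1 * (c_right - c_left))
        if (is.null(tr)) {
          lt <- list(t = numeric(), mv = numeric())
        } else {
          sel <- tr$columns >= c0 & tr$columns < c1
          mv <- tr$mv[sel]
          mv <- mv - median(mv, na.rm = TRUE)
          lt <- list(t = strip_leads$t0[li] +
                       (tr$columns[sel] - c0) * sec_per_px, mv = mv)
        }
        # rhythm strips take precedence for their lead
        if (is.null(traces[[lead]]) || strip_leads$rhythm[li]) {
          traces[[lead]] <- lt
        }
      }
    }
  } else {
    note("no (or too little) signal detected; emitting an all-NA record")
  }
  for (lead in unique(template$panels$lead)) {
    if (is.null(traces[[lead]])) traces[[lead]] <- list(t = numeric(),
                                                        mv = numeric())
  }
  rec <- assemble_record(traces, duration_s = template$duration_s,
                         target_rate = config$target_rate,
                         calibration = calib, layout_name = template$name,
                         warnings = warnings)
  if (!is.null(config$debug_dir)) {
    tryCatch(write_debug_bundle(config$debug_dir, image, probs, dew, calib,
                                markers, match, rec),
             error = function(e) NULL)
  }
  rec
}

# Debug artifacts: per-stage images and a status JSON.
write_debug_bundle <- function(dir, image, probs, dew, calib, markers,
                               match, rec) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  overlay <- image
  cls <- argmax_planes(probs)$which
  tint <- list(NULL, c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  for (k in 2:4) {
    sel <- cls == k
    for (ch in 1:3) {
      pl <- overlay[, , ch]
      pl[sel] <- 0.5 * pl[sel] + 0.5 * tint[[k]][ch]
      overlay[, , ch] <- pl
    }
  }
  write_image(overlay, file.path(dir, "segmentation_overlay.png"))
  write_image(dew$image, file.path(dir, "dewarped.png"))
  marked <- dew$image
  if (!is.null(markers) && nrow(markers)) {
    for (i in seq_len(nrow(markers))) {
      rr <- clamp(round(markers$y[i]) + (-2:2), 0, nrow(marked) - 1) + 1
      cc <- clamp(round(markers$x[i]) + (-2:2), 0, ncol(marked) - 1) + 1
      marked[rr, cc, 1] <- 1; marked[rr, cc, 2] <- 0; marked[rr, cc, 3] <- 0
    }
  }
  write_image(marked, file.path(dir, "layout_markers.png"))
  png_path <- file.path(dir, "traces.png")
  grDevices::png(png_path, 1200, 800)
  on.exit(grDevices::dev.off())
  leads <- rec$leads
  graphics::par(mfrow = c(length(leads), 1), mar = c(0.5, 4, 0.5, 0.5))
  tt <- (seq_len(nrow(rec$samples)) - 1) / rec$rate
  for (lead in leads) {
    graphics::plot(tt, rec$samples[, lead], type = "l", ylab = lead,
                   xaxt = "n")
  }
  status <- list(
    dewarp = list(crop = dew$crop, had_signal = isTRUE(dew$had_signal)),
    calibration = calib[c("d_px_x", "d_px_y", "speed_mm_per_s",
                          "gain_mm_per_mV")],
    layout = list(name = match$template$name, cost = match$cost,
                  fallback = isTRUE(match$fallback)),
    n_markers = if (is.null(markers)) 0L else nrow(markers),
    warnings = rec$warnings)
  jsonlite::write_json(status, file.path(dir, "status.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}
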