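# Resampling and cropping after the two grid-line families are known. The
# homography sends both families' vanishing points to ideal points along the
# image axes; the residual affine freedom is fixed by preserving unit scale
# at the image center, forbidding flips, and equalizing the recovered grid
# spacing on the two axes (feedback from the autocorrelation spacing
# estimator).

jacobian_at <- function(h, p) {
  ph <- c(p, 1)
  w <- sum(h[3, ] * ph)
  f1 <- sum(h[1, ] * ph) / w
  f2 <- sum(h[2, ] * ph) / w
  rbind((h[1, 1:2] - f1 * h[3, 1:2]) / w,
        (h[2, 1:2] - f2 * h[3, 1:2]) / w)
}

#' Rectify an image and its probability maps from two line families
#'
#' @param image H x W x 3 array (or H x W matrix).
#' @param maps H x W x C array of class probabilities (class order
#'   background, grid, signal, text).
#' @param families List of two `line_family` objects from
#'   [find_line_families()] (horizontal family first).
#' @param crop_margin_mm Margin kept around the signal bounding box, in
#'   grid-spacing units of 1 mm (default 10, i.e. two major squares).
#' @param equalize_axes Rescale the vertical axis so both grid spacings
#'   match (default TRUE).
#' @param map_interp Interpolation for the probability maps: `"bilinear"`
#'   (default, for soft network outputs) or `"nearest"` (for crisp label
#'   maps, avoiding probability smearing).
#' @return A `dewarped_sample`: list with `image`, `probs`, `homography`
#'   (original -> rectified pixel coordinates, before cropping), `crop`
#'   (r0, r1, c0, c1; 1-based, in rectified coordinates), `d_provisional`
#'   (grid spacings measured during equalization) and `signal_bbox` (in
#'   cropped coordinates).
#' @export
rectify <- function(image, maps, families, crop_margin_mm = 10,
                    equalize_axes = TRUE,
                    map_interp = c("bilinear", "nearest")) {
  map_interp <- match.arg(map_interp)
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  h_img <- dim(image)[1]; w_img <- dim(image)[2]
  v_h <- family_vanishing_point(families[[1]])
  v_v <- family_vanishing_point(families[[2]])
  l <- c(v_h[2] * v_v[3] - v_h[3] * v_v[2],
         v_h[3] * v_v[1] - v_h[1] * v_v[3],
         v_h[1] * v_v[2] - v_h[2] * v_v[1])
  if (sqrt(sum(l^2)) < 1e-12) dewarp_failure("degenerate vanishing points")
  if (abs(l[3]) < 1e-12 * max(abs(l[1:2]))) {
    dewarp_failure("vanishing line through the origin")
  }
  p_mat <- rbind(c(1, 0, 0), c(0, 1, 0), c(l[1] / l[3], l[2] / l[3], 1))
  dh <- (p_mat %*% v_h)[1:2]
  dv <- (p_mat %*% v_v)[1:2]
  # normalize the family directions: vanishing-point coordinates carry
  # arbitrary magnitudes, and an unnormalized basis makes the affine part
  # violently anisotropic
  dh <- dh / sqrt(sum(dh^2))
  dv <- dv / sqrt(sum(dv^2))
  m_dir <- cbind(dh, dv)
  if (abs(det(m_dir)) < 1e-12) dewarp_failure("parallel vanishing directions")
  a2 <- solve(m_dir)
  hmat <- rbind(cbind(a2, c(0, 0)), c(0, 0, 1)) %*% p_mat
  center <- c((w_img - 1) / 2, (h_img - 1) / 2)
  j <- jacobian_at(hmat, center)
  if (j[1, 1] < 0) hmat[1, ] <- -hmat[1, ]
  if (jacobian_at(hmat, center)[2, 2] < 0) hmat[2, ] <- -hmat[2, ]
  j <- jacobian_at(hmat, center)
  sx <- 1 / sqrt(sum(j[, 1]^2)); sy <- 1 / sqrt(sum(j[, 2]^2))
  hmat <- diag(c(sx, sy, 1)) %*% hmat

  warp_all <- function(hh) {
    corners <- apply_homography(hh, rbind(c(0, 0), c(w_img - 1, 0),
                                          c(w_img - 1, h_img - 1),
                                          c(0, h_img - 1)))
    tr <- diag(3)
    tr[1, 3] <- -min(corners[, 1])
    tr[2, 3] <- -min(corners[, 2])
    hh <- tr %*% hh
    out_w <- ceiling(diff(range(corners[, 1]))) + 1L
    out_h <- ceiling(diff(range(corners[, 2]))) + 1L
    list(h = hh, out_h = out_h, out_w = out_w)
  }

  d_prov <- c(NA_real_, NA_real_)
  if (equalize_axes) {
    wa <- warp_all(hmat)
    grid_rect <- warp_image(maps[, , 2], wa$h, wa$out_h, wa$out_w, "bilinear")
    est <- tryCatch({
      ex <- estimate_spacing_from_map(grid_rect, "horizontal")
      ey <- estimate_spacing_from_map(grid_rect, "vertical")
      c(ex$d_px, ey$d_px)
    }, calibration_failure = function(e) NULL, error = function(e) NULL)
    if (!is.null(est)) {
      d_prov <- est
      hmat <- diag(c(1, est[1] / est[2], 1)) %*% hmat
    }
  }
  wa <- warp_all(hmat)
  img_r <- warp_image(image, wa$h, wa$out_h, wa$out_w, "bilinear", fill = 0)
  n_cls <- dim(maps)[3]
  probs_r <- array(0, c(wa$out_h, wa$out_w, n_cls))
  for (c in seq_len(n_cls)) {
    probs_r[, , c] <- warp_image(maps[, , c], wa$h, wa$out_h, wa$out_w,
                                 map_interp, fill = 0)
  }

  d_ref <- if (is.finite(d_prov[1])) d_prov[1] else 5
  margin <- round(crop_margin_mm * d_ref)
  sig <- probs_r[, , 3] > 0.5
  if (any(sig)) {
    rr <- range(which(rowSums(sig) > 0))
    cc <- range(which(colSums(sig) > 0))
  } else {
    rr <- c(1L, wa$out_h); cc <- c(1L, wa$out_w)
  }
  crop <- c(max(1L, rr[1] - margin), min(wa$out_h, rr[2] + margin),
            max(1L, cc[1] - margin), min(wa$out_w, cc[2] + margin))
  img_c <- img_r[crop[1]:crop[2], crop[3]:crop[4], , drop = FALSE]
  probs_c <- probs_r[crop[1]:crop[2], crop[3]:crop[4], , drop = FALSE]
  # renormalize probabilities after interpolation (cropped region only)
  tot <- probs_c[, , 1]
  for (c in 2:n_cls) tot <- tot + probs_c[, , c]
  tot[tot < 1e-9] <- 1e-9
  for (c in seq_len(n_cls)) probs_c[, , c] <- probs_c[, , c] / tot
  structure(list(image = img_c, probs = probs_c, homography = wa$h,
                 crop = crop, d_provisional = d_prov,
                 signal_bbox = c(rr[1] - crop[1] + 1L, rr[2] - crop[1] + 1L,
                                 cc[1] - crop[3] + 1L, cc[2] - crop[3] + 1L),
                 had_signal = any(sig)),
            class = "dewarped_sample")
}

# Warp an extra plane with a dewarped sample's recorded transform, straight
# into its crop box (memory-friendly: one crop-sized plane at a time).
warp_into_crop <- function(plane, dew, mode = "bilinear", fill = 0) {
  out_h <- dew$crop[2] - dew$crop[1] + 1L
  out_w <- dew$crop[4] - dew$crop[3] + 1L
  tr <- diag(3)
  tr[1, 3] <- dew$crop[3] - 1L
  tr[2, 3] <- dew$crop[1] - 1L
  warp_image(plane, solve(tr) %*% dew$homography, out_h, out_w, mode, fill)
}

# convenience: spacing estimate straight from a grid map
estimate_spacing_from_map <- function(grid_map, axis, d_range = c(3, 80)) {
  prof <- axis_profile(grid_map, axis)
  m_max <- min(length(prof$values) - 1L,
               floor(length(prof$values) / 2),
               round(25 * d_range[2]))
  if (m_max < 2 * d_range[1]) {
    calibration_failure("profile too short for spacing estimation")
  }
  ac <- autocorrelation(prof, m_max)
  d_hi <- min(d_range[2], floor(m_max / 2))
  estimate_spacing(ac, c(d_range[1], d_hi))
}

#' Rectify with a pure rotation (fallback path)
#'
#' @param image Image array.
#' @param maps Probability array.
#' @param angle Rotation to remove, radians (as from [estimate_rotation()]).
#' @inheritParams rectify
#' @return A `dewarped_sample` (axes are not re-scaled).
#' @export
rectify_rotation <- function(image, maps, angle, crop_margin_mm = 10,
                             map_interp = "bilinear") {
  fam_h <- structure(list(theta_rho_min = pi / 2 + angle,
                          theta_rho_max = pi / 2 + angle,
                          rho_min = 0, rho_max = 1, pool = 1L, strength = 0),
                     class = "line_family")
  fam_v <- structure(list(theta_rho_min = angle, theta_rho_max = angle,
                          rho_min = 0, rho_max = 1, pool = 1L, strength = 0),
                     class = "line_family")
  rectify(image, maps, list(fam_h, fam_v), crop_margin_mm,
          equalize_axes = FALSE, map_interp = map_interp)
}
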