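# Perspective estimation from the grid probability map. Grid lines satisfy
# y sin(theta) + x cos(theta) = rho (x = 0-based column, y = 0-based row,
# angles from the +x axis). Each set of nearly parallel grid lines forms a
# line in the angle-radius (Hough) domain; that line is located as a maximum
# of the angle-angle transform, whose value at (theta_i, theta_j) is the
# variance of accumulator samples along the segment joining
# (theta_i, rho_min) and (theta_j, rho_max).

#' Hough transform of a grid probability map
#'
#' Every pixel votes its probability mass into the bins
#' `(theta, rho = x cos theta + y sin theta)` for every angle of
#' `theta_axis`, with linear interpolation between the two neighbouring rho
#' bins. Voting is linear in the map: `hough(a*m) = a*hough(m)`.
#'
#' @param grid_map Matrix of grid-class probabilities in \[0, 1\].
#' @param theta_axis Ordered vector of angles (radians).
#' @param rho_resolution Rho bin width in pixels (default 1).
#' @return A `hough_accumulator`: list with `theta_axis`, `rho_axis` (bin
#'   centers) and `votes` (angles x rho bins).
#' @export
hough_transform <- function(grid_map, theta_axis, rho_resolution = 1) {
  if (any(grid_map < -1e-9) || any(grid_map > 1 + 1e-9)) {
    stop("grid_map values must be in [0, 1]")
  }
  h <- nrow(grid_map); w <- ncol(grid_map)
  diag_len <- sqrt(h^2 + w^2)
  rho_min <- -diag_len
  n_rho <- ceiling(2 * diag_len / rho_resolution) + 1L
  votes <- hough_accum(grid_map, theta_axis, rho_min, rho_resolution, n_rho)
  structure(list(theta_axis = theta_axis,
                 rho_axis = rho_min + (seq_len(n_rho) - 1) * rho_resolution,
                 votes = votes),
            class = "hough_accumulator")
}

#' Angle-angle transform of a Hough accumulator
#'
#' @param acc A `hough_accumulator` with at least 2 rho bins.
#' @return Square matrix over `acc$theta_axis`; entry (i, j) is the variance
#'   of the accumulator sampled along the line from `(theta_i, rho_min)` to
#'   `(theta_j, rho_max)` (one bilinear sample per rho bin).
#' @export
angle_angle_transform <- function(acc) {
  if (length(acc$rho_axis) < 2) stop("accumulator needs >= 2 rho bins")
  m <- angle_angle(acc$votes)
  dimnames(m) <- NULL
  attr(m, "theta_axis") <- acc$theta_axis
  m
}

dewarp_failure <- function(msg) {
  stop(errorCondition(msg, class = c("dewarp_failure", "error", "condition")))
}

# rho bins holding appreciable (sharpened) vote mass, as a [lo, hi] index
# pair; falls back to the full range for empty accumulators
occupied_band <- function(votes, frac = 0.2) {
  o <- colSums(votes)
  idx <- which(o > frac * max(o))
  if (length(idx) < 2) return(c(1L, ncol(votes)))
  range(idx)
}

# High-pass the accumulator along rho (subtract a running mean per angle,
# clamp at zero). Grid-line combs survive; the slowly varying background
# mass collected by arbitrary lines through the image is removed, which
# makes the angle-angle maxima orders of magnitude more prominent.
sharpen_accumulator <- function(votes, win = 25L) {
  filt <- stats::filter(t(votes), rep(1 / win, win), sides = 2)
  filt[is.na(filt)] <- 0
  out <- votes - t(filt)
  out[out < 0] <- 0
  out
}

#' Locate the two dominant grid-line families
#'
#' Runs a coarse Hough transform over \[-pi/4, 3pi/4\], finds the two most
#' prominent angle-angle maxima separated by about pi/2, then refines each
#' with a fine Hough/angle-angle pass. Large maps are max-pooled before
#' voting so the long side is at most `max_side` pixels.
#'
#' @param grid_map Grid-class probability matrix.
#' @param coarse_step_deg Coarse angular resolution (default 0.5).
#' @param fine_step_deg Fine resolution (default 0.02).
#' @param fine_halfwidth_deg Zoom half-width around each coarse angle
#'   (default 2).
#' @param prominence Minimum ratio of the peak value to the median
#'   angle-angle value over admissible pairs (default 50); weaker peaks
#'   raise a dewarp failure.
#' @param sep_tol_deg Allowed deviation of the family separation from 90
#'   degrees (default 15).
#' @param max_spread_deg Largest admissible in-family angle spread
#'   `|theta_i - theta_j|` (default 25); larger spreads do not occur for
#'   plausible perspectives and are artifact-prone.
#' @param max_side Pooled map long-side bound (default 2048).
#' @return List of two `line_family` objects (`theta_rho_min`,
#'   `theta_rho_max`, `rho_min`, `rho_max`, `pool`, `strength`), the first
#'   being the more horizontal family. Raises a condition of class
#'   `dewarp_failure` if no two well-separated families are found.
#' @export
find_line_families <- function(grid_map, coarse_step_deg = 0.5,
                               fine_step_deg = 0.02, fine_halfwidth_deg = 2,
                               prominence = 50, sep_tol_deg = 15,
                               max_spread_deg = 25, max_side = 2048) {
  if (sum(grid_map) <= 0) dewarp_failure("empty grid map")
  pool <- max(1L, ceiling(max(dim(grid_map)) / max_side))
  pooled <- if (pool > 1L) maxpool_factor(grid_map, pool) else grid_map

  step <- coarse_step_deg * pi / 180
  thetas <- seq(-pi / 4, 3 * pi / 4, by = step)
  acc <- hough_transform(pooled, thetas, rho_resolution = 1)
  acc$votes <- sharpen_accumulator(acc$votes)
  # restrict to the rho band actually occupied by line mass: outside it the
  # angle-angle segments are unconstrained and the maxima smear into ridges
  occ <- occupied_band(acc$votes)
  acc$votes <- acc$votes[, occ[1]:occ[2], drop = FALSE]
  acc$rho_axis <- acc$rho_axis[occ[1]:occ[2]]
  aa <- angle_angle_transform(acc)
  spread_ok <- abs(outer(thetas, thetas, `-`)) <= max_spread_deg * pi / 180
  base <- median(aa[spread_ok])
  if (base <= 0) base <- mean(aa[spread_ok]) / 10
  if (base <= 0) dewarp_failure("flat angle-angle map")

  mean_angle <- function(idx) (thetas[idx[1]] + thetas[idx[2]]) / 2
  aa1 <- aa
  aa1[!spread_ok] <- -Inf
  p1 <- arrayInd(which.max(aa1), dim(aa1))
  ang1 <- mean_angle(p1)
  if (aa1[p1] < prominence * base) dewarp_failure("no prominent line family")
  # search the second family near the orthogonal mean angle (mod pi)
  dang <- outer(thetas, thetas, function(a, b) (a + b) / 2)
  dd <- abs(((dang - ang1) + pi / 2) %% pi - pi / 2)
  aa2 <- aa
  aa2[!spread_ok | dd < pi / 2 - sep_tol_deg * pi / 180] <- -Inf
  p2 <- arrayInd(which.max(aa2), dim(aa2))
  if (!is.finite(aa2[p2]) || aa2[p2] < prominence * base) {
    dewarp_failure("no second line family")
  }

  refine <- function(peak) {
    ti <- thetas[peak[1]]; tj <- thetas[peak[2]]
    hw <- fine_halfwidth_deg * pi / 180
    # medium-resolution pass over the whole family window with the family's
    # own occupied rho band (other families' mass is smooth in rho here and
    # is removed by sharpening)
    mstep <- max(fine_step_deg, 0.2) * pi / 180
    mthetas <- seq(min(ti, tj) - hw, max(ti, tj) + hw, by = mstep)
    macc <- hough_transform(pooled, mthetas, rho_resolution = 1)
    macc$votes <- sharpen_accumulator(macc$votes)
    mocc <- occupied_band(macc$votes)
    mv <- macc$votes[, mocc[1]:mocc[2], drop = FALSE]
    rho_lo <- macc$rho_axis[mocc[1]]; rho_hi <- macc$rho_axis[mocc[2]]
    sub <- angle_angle_sub(mv, 0L, length(mthetas) - 1L,
                           0L, length(mthetas) - 1L)
    best <- arrayInd(which.max(sub), dim(sub))
    ti2 <- mthetas[best[1]]; tj2 <- mthetas[best[2]]
    # fine pass at full resolution in narrow windows around the estimates
    fstep <- fine_step_deg * pi / 180
    fhw <- 2 * mstep
    fthetas <- seq(min(ti2, tj2) - fhw, max(ti2, tj2) + fhw, by = fstep)
    facc <- hough_transform(pooled, fthetas, rho_resolution = 1)
    facc$votes <- sharpen_accumulator(facc$votes)
    focc <- occupied_band(facc$votes)
    fv <- facc$votes[, focc[1]:focc[2], drop = FALSE]
    rho_lo <- facc$rho_axis[focc[1]]; rho_hi <- facc$rho_axis[focc[2]]
    ii <- which(abs(fthetas - ti2) <= fhw + 1e-12)
    jj <- which(abs(fthetas - tj2) <= fhw + 1e-12)
    sub <- angle_angle_sub(fv, min(ii) - 1L, max(ii) - 1L,
                           min(jj) - 1L, max(jj) - 1L)
    best <- arrayInd(which.max(sub), dim(sub))
    structure(list(theta_rho_min = fthetas[ii[best[1]]],
                   theta_rho_max = fthetas[jj[best[2]]],
                   rho_min = rho_lo * pool,
                   rho_max = rho_hi * pool,
                   pool = pool, strength = max(sub)),
              class = "line_family")
  }
  fams <- list(refine(p1), refine(p2))
  # order: first family = more horizontal lines (mean angle nearer pi/2)
  ma <- vapply(fams, function(f) (f$theta_rho_min + f$theta_rho_max) / 2, 0)
  horiz_first <- order(-abs(sin(ma)))
  fams[horiz_first]
}

# Vanishing point (homogeneous) of a line family: intersection of its two
# extreme lines (theta_a, rho_min) and (theta_b, rho_max). Near-parallel
# families give an ideal point along the line direction.
family_vanishing_point <- function(fam) {
  a <- fam$theta_rho_min; b <- fam$theta_rho_max
  if (abs(a - b) < 1e-9) {
    return(c(-sin(a), cos(a), 0))
  }
  m <- rbind(c(cos(a), sin(a)), c(cos(b), sin(b)))
  rhs <- c(fam$rho_min, fam$rho_max)
  det_m <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det_m) < 1e-12) return(c(-sin(a), cos(a), 0))
  p <- solve(m, rhs)
  c(p, 1)
}

#' Estimate a pure rotation from the grid map
#'
#' Fallback used when full line-family detection fails: picks the angle
#' whose Hough accumulator row has maximal variance and returns the rotation
#' (in radians) that would make that family axis-aligned.
#'
#' @param grid_map Grid-class probability matrix.
#' @param step_deg Angular resolution.
#' @return Rotation angle in radians (0 when the map is empty).
#' @export
estimate_rotation <- function(grid_map, step_deg = 0.25) {
  if (sum(grid_map) <= 0) return(0)
  pool <- max(1L, ceiling(max(dim(grid_map)) / 1024))
  pooled <- if (pool > 1L) maxpool_factor(grid_map, pool) else grid_map
  thetas <- seq(-pi / 4, pi / 4, by = step_deg * pi / 180)
  acc <- hough_transform(pooled, thetas, rho_resolution = 1)
  v <- apply(acc$votes, 1, var)
  thetas[which.max(v)]
}
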