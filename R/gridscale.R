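# Grid-spacing calibration. The dewarped grid probability map is collapsed
# to a 1D profile per axis, its autocorrelation R_xx[m] = sum_n x[n] x[n+m]
# exposes the grid periodicity, and a comb template with minor peaks at
# multiples of d and amplified peaks at multiples of 5d is matched to the
# (detrended) autocorrelation by an adaptive grid search over d.

#' Collapse a grid map to a 1D axis profile
#'
#' @param grid_map Dewarped grid-class probability matrix.
#' @param axis `"horizontal"` (per-column sums; vertical grid lines appear
#'   as peaks) or `"vertical"` (per-row sums).
#' @return An `axis_profile`: list with `values` and `axis`.
#' @export
axis_profile <- function(grid_map, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  values <- if (axis == "horizontal") colSums(grid_map) else rowSums(grid_map)
  structure(list(values = as.numeric(values), axis = axis),
            class = "axis_profile")
}

#' Exact discrete autocorrelation of an axis profile
#'
#' `R_xx[m] = sum_n x[n] * x[n + m]` over all valid indices (no
#' wrap-around).
#'
#' @param profile An `axis_profile` (or numeric vector).
#' @param m_max Largest lag; must be smaller than the profile length.
#' @return An `autocorr_profile`: list with `lags` (0..m_max) and `values`.
#' @export
autocorrelation <- function(profile, m_max) {
  x <- if (inherits(profile, "axis_profile")) profile$values else as.numeric(profile)
  if (m_max >= length(x)) stop("m_max must be smaller than the profile length")
  structure(list(lags = 0:m_max, values = as.numeric(autocorr_raw(x, m_max)),
                 n = length(x),
                 axis = if (inherits(profile, "axis_profile")) profile$axis else NA),
            class = "autocorr_profile")
}

calibration_failure <- function(msg) {
  stop(errorCondition(msg, class = c("calibration_failure", "error", "condition")))
}

# comb template on integer lags 1..m for candidate spacing d: unit Gaussian
# bumps at multiples of d, amplified at multiples of 5d, damped by the
# natural triangular decay (1 - m/n) of an n-sample autocorrelation. The
# bump width follows the spacing (sd = d/12) but is capped: autocorrelation
# peak widths are set by the ruling line width (a couple of pixels), not by
# the spacing, and an uncapped width lets the d/5 subharmonic outscore the
# true spacing on coarse grids.
comb_template <- function(d, m, n_env = 2 * m, w_major = 1.5) {
  lags <- seq_len(m)
  tpl <- numeric(m)
  sd_b <- max(0.4, min(d / 12, 1.2))
  for (k in seq_len(floor(m / d) + 1L)) {
    mu <- k * d
    wgt <- if (k %% 5 == 0) w_major else 1
    lo <- max(1L, floor(mu - 4 * sd_b)); hi <- min(m, ceiling(mu + 4 * sd_b))
    if (lo > hi) next
    idx <- lo:hi
    tpl[idx] <- tpl[idx] + wgt * exp(-((idx - mu)^2) / (2 * sd_b^2))
  }
  tpl * pmax(0, 1 - lags / n_env)
}

# running mean with centred window (odd), edges padded by reflection
running_mean <- function(x, win) {
  win <- max(3L, as.integer(win))
  if (win %% 2 == 0) win <- win + 1L
  half <- (win - 1L) %/% 2L
  n <- length(x)
  xp <- c(rev(x[seq_len(min(half, n))]), x, rev(x[seq.int(max(1, n - half + 1), n)]))
  cs <- cumsum(c(0, xp))
  (cs[(win + 1):(win + n)] - cs[seq_len(n)]) / win
}

score_spacing <- function(ac_vals, d, m_max, n_env, n_periods = Inf) {
  m_used <- min(m_max, length(ac_vals) - 1L, ceiling(n_periods * d))
  if (m_used < 2 * d) return(-Inf)
  y <- ac_vals[1 + seq_len(m_used)] # lags 1..m_used
  base <- running_mean(y, round(d) + (1 - round(d) %% 2))
  yd <- y - base
  tpl <- comb_template(d, m_used, n_env)
  if (sd(tpl) == 0 || sd(yd) == 0) return(-Inf)
  suppressWarnings(stats::cor(yd, tpl))
}

#' Estimate the minor-grid spacing from an autocorrelation profile
#'
#' Coarse grid search over candidate spacings followed by iterative
#' refinement (step shrunk by 0.2 per round until below 0.01 px). The score
#' is the Pearson correlation between the moving-average-detrended
#' autocorrelation and the 1d/5d comb template.
#'
#' @param autocorr An `autocorr_profile`.
#' @param d_range Candidate spacing range in pixels (default c(3, 80)).
#' @param coarse_step Coarse search step (default 0.25 px).
#' @param refine_rounds Refinement rounds (default 4).
#' @param min_score Below this best score a condition of class
#'   `calibration_failure` is raised (default 0.2).
#' @return A `grid_estimate`: list with `d_px`, `score`, `axis`.
#' @export
estimate_spacing <- function(autocorr, d_range = c(3, 80), coarse_step = 0.25,
                             refine_rounds = 4, min_score = 0.2) {
  vals <- autocorr$values
  m_max <- max(autocorr$lags)
  n_env <- autocorr$n %||% (2 * m_max)
  if (d_range[1] <= 0 || d_range[2] <= d_range[1]) stop("invalid d_range")
  if (d_range[2] > m_max / 2) d_range[2] <- max(d_range[1] + 1, m_max / 2)
  # coarse scoring uses few comb periods (a broad, step-robust peak); each
  # refinement round extends the window, sharpening the peak as the step
  # shrinks
  cand <- seq(d_range[1], d_range[2], by = coarse_step)
  scores <- vapply(cand, function(d) score_spacing(vals, d, m_max, n_env, 10), 0)
  best <- which.max(scores)
  if (!is.finite(scores[best])) calibration_failure("flat autocorrelation")
  d_best <- cand[best]
  step <- coarse_step
  periods <- 10
  for (r in seq_len(refine_rounds)) {
    step <- step * 0.2
    periods <- if (r == refine_rounds) Inf else periods * 2.5
    cand <- seq(max(d_range[1], d_best - 10 * step),
                min(d_range[2], d_best + 10 * step), by = step)
    scores <- vapply(cand,
                     function(d) score_spacing(vals, d, m_max, n_env, periods), 0)
    d_best <- cand[which.max(scores)]
  }
  score <- max(scores)
  if (!is.finite(score) || score < min_score) {
    calibration_failure(sprintf("no grid periodicity found (score %.3f)", score))
  }
  structure(list(d_px = d_best, score = score,
                 axis = autocorr$axis %||% NA), class = "grid_estimate")
}

#' Convert grid-spacing estimates to a physical calibration
#'
#' The minor grid spacing corresponds to 1 mm, so `d_px` is pixels per mm;
#' combined with the paper constants this yields seconds and millivolts per
#' pixel.
#'
#' @param est_x,est_y `grid_estimate`s for the horizontal and vertical axes
#'   (or bare numbers, pixels per mm).
#' @param speed_mm_per_s Paper speed (mm/s).
#' @param gain_mm_per_mV Paper gain (mm/mV).
#' @return A `calibration`: list with `d_px_x`, `d_px_y`, the paper
#'   constants, `seconds_per_px` and `mV_per_px`.
#' @export
to_physical <- function(est_x, est_y, speed_mm_per_s = 25,
                        gain_mm_per_mV = 10) {
  dx <- if (inherits(est_x, "grid_estimate")) est_x$d_px else est_x
  dy <- if (inherits(est_y, "grid_estimate")) est_y$d_px else est_y
  if (any(c(dx, dy, speed_mm_per_s, gain_mm_per_mV) <= 0)) {
    stop("calibration inputs must be positive")
  }
  structure(list(d_px_x = dx, d_px_y = dy,
                 speed_mm_per_s = speed_mm_per_s,
                 gain_mm_per_mV = gain_mm_per_mV,
                 seconds_per_px = 1 / (dx * speed_mm_per_s),
                 mV_per_px = 1 / (dy * gain_mm_per_mV)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.3f px/mm (x), %.3f px/mm (y), %g mm/s, %g mm/mV\n",
              x$d_px_x, x$d_px_y, x$speed_mm_per_s, x$gain_mm_per_mV))
  invisible(x)
}
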