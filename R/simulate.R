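#' Simulate a multi-lead ECG waveform
#'
#' Generates quasi-periodic P-QRS-T waveforms as a sum of five Gaussian waves
#' per beat. Lead I and lead II are generated as independent projections of
#' the same beat train, and the remaining limb leads are derived from them
#' (III = II - I, aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2), so the
#' limb-lead identities hold exactly. Precordial leads V1-V6 receive their own
#' amplitude profiles, emulating the R-wave progression across the chest.
#'
#' @param n_leads Number of leads, taken in the standard order
#'   I, II, III, aVR, aVL, aVF, V1-V6. Default 12.
#' @param duration_s Duration in seconds (> 0).
#' @param rate Sample rate in Hz (> 0).
#' @param morphology Optional list overriding morphology defaults:
#'   `heart_rate_bpm` (default 60), `rr_jitter` (relative s.d. of RR
#'   intervals, 0.02), `amp_jitter` (relative beat-to-beat amplitude jitter,
#'   0.05), `baseline_mv` (baseline-wander amplitude in mV, 0), `noise_mv`
#'   (white-noise s.d. in mV, 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `multi_lead_signal`: a list with `lead_names`,
#'   `samples` (numeric matrix, one column per lead, millivolts) and `rate`.
#' @export
simulate_ecg <- function(n_leads = 12, duration_s = 10, rate = 500,
                         morphology = list(), seed = 1) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  if (n_leads < 1 || n_leads > 12) stop("n_leads must be in 1..12")
  m <- modifyList(list(heart_rate_bpm = 60, rr_jitter = 0.02,
                       amp_jitter = 0.05, baseline_mv = 0, noise_mv = 0),
                  morphology)
  leads <- LEAD_NAMES[seq_len(n_leads)]
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  # beat train: R-peak times with mild RR variability
  rr <- 60 / m$heart_rate_bpm
  n_beats <- ceiling(duration_s / rr) + 2
  rrs <- rr * (1 + m$rr_jitter * rnorm(n_beats))
  peaks <- cumsum(c(0.45 * rr, rrs))
  peaks <- peaks[peaks < duration_s + 0.5]

  # wave offsets (s from R peak), widths (s) and base amplitudes (mV) for a
  # "lead II like" beat; per-lead scale factors below
  wave_mu <- c(P = -0.17, Q = -0.04, R = 0, S = 0.04, T = 0.26)
  wave_sd <- c(P = 0.022, Q = 0.010, R = 0.013, S = 0.012, T = 0.055)
  base_amp <- c(P = 0.12, Q = -0.12, R = 1.0, S = -0.25, T = 0.30)

  # per-lead multipliers of the base wave amplitudes (I, II and V1-V6 are
  # generative; III/aVR/aVL/aVF are derived)
  lead_scale <- list(
    I  = c(P = 0.7, Q = 0.6, R = 0.65, S = 0.6, T = 0.8),
    II = c(P = 1.0, Q = 1.0, R = 1.0,  S = 1.0, T = 1.0),
    V1 = c(P = 0.4, Q = 0.0, R = 0.25, S = 2.2, T = -0.5),
    V2 = c(P = 0.5, Q = 0.0, R = 0.45, S = 2.4, T = 0.9),
    V3 = c(P = 0.5, Q = 0.2, R = 0.75, S = 1.6, T = 1.1),
    V4 = c(P = 0.6, Q = 0.5, R = 1.25, S = 0.9, T = 1.0),
    V5 = c(P = 0.6, Q = 0.7, R = 1.15, S = 0.5, T = 0.9),
    V6 = c(P = 0.6, Q = 0.8, R = 0.95, S = 0.25, T = 0.8)
  )

  beat_jitter <- matrix(1 + m$amp_jitter * rnorm(length(peaks) * 5),
                        length(peaks), 5)

  gen_lead <- function(scale) {
    y <- numeric(n)
    for (b in seq_along(peaks)) {
      for (w in seq_along(wave_mu)) {
        a <- base_amp[w] * scale[w] * beat_jitter[b, w]
        if (a == 0) next
        mu <- peaks[b] + wave_mu[w]
        y <- y + a * exp(-((t - mu)^2) / (2 * wave_sd[w]^2))
      }
    }
    y
  }

  gens <- lapply(lead_scale, gen_lead)
  full <- list(
    I = gens$I, II = gens$II, III = gens$II - gens$I,
    aVR = -(gens$I + gens$II) / 2, aVL = gens$I - gens$II / 2,
    aVF = gens$II - gens$I / 2,
    V1 = gens$V1, V2 = gens$V2, V3 = gens$V3, V4 = gens$V4,
    V5 = gens$V5, V6 = gens$V6
  )
  samples <- do.call(cbind, full[leads])

  if (m$baseline_mv > 0) {
    f <- runif(1, 0.15, 0.4)
    ph <- runif(1, 0, 2 * pi)
    samples <- samples + m$baseline_mv * sin(2 * pi * f * t + ph)
  }
  if (m$noise_mv > 0) {
    samples <- samples + matrix(m$noise_mv * rnorm(length(samples)),
                                nrow = n)
  }
  colnames(samples) <- leads
  structure(list(lead_names = leads, samples = samples, rate = rate),
            class = "multi_lead_signal")
}

#' @export
print.multi_lead_signal <- function(x, ...) {
  cat(sprintf("<multi_lead_signal> %d leads x %d samples @ %g Hz (%s)\n",
              length(x$lead_names), nrow(x$samples), x$rate,
              paste(x$lead_names, collapse = ", ")))
  invisible(x)
}
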