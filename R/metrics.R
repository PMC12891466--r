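# Evaluation metrics: shifted SNR, RMSE and correlation. Reconstruction and
# truth are aligned by an integer-sample horizontal shift (bounded) and by
# zero-centering both series; NA samples in the reconstruction are scored as
# zeros on the centred scale (a strict mode excludes them instead).

#' Align a reconstruction to the ground truth
#'
#' Both series are mean-centred (the reconstruction's centre uses its finite
#' samples only); the integer-sample shift within `+-max_shift_ms` that
#' maximizes SNR on the overlap is selected, re-centring per candidate
#' window.
#'
#' @param y Ground-truth series (mV, finite).
#' @param y_hat Reconstruction (mV, NA allowed), same rate.
#' @param max_shift_ms Shift bound in milliseconds (default 100).
#' @param rate Sample rate in Hz (default 1000).
#' @param nan_mode `"zero"` (default) scores NA as 0 after centring;
#'   `"strict"` excludes NA samples from all sums.
#' @return List with `shift_ms`, `y` and `y_hat` (centred, aligned, equal
#'   length) and `nan_frac`.
#' @export
align_signals <- function(y, y_hat, max_shift_ms = 100, rate = 1000,
                          nan_mode = c("zero", "strict")) {
  nan_mode <- match.arg(nan_mode)
  n <- length(y)
  if (length(y_hat) != n) {
    stop("series lengths differ; resample before alignment")
  }
  s_max <- round(max_shift_ms / 1000 * rate)
  if (n - s_max < 2) stop("series too short for the requested shift range")
  best <- NULL
  for (k in -s_max:s_max) {
    # aligned reconstruction: y_hat_k[i] = y_hat[i + k]
    i0 <- max(1L, 1L - k); i1 <- min(n, n - k)
    yi <- y[i0:i1]
    hi <- y_hat[(i0 + k):(i1 + k)]
    yc <- yi - mean(yi)
    fin <- is.finite(hi)
    hc <- hi - mean(hi[fin])
    if (nan_mode == "zero") {
      hc[!fin] <- 0
      num <- sum(yc^2); den <- sum((yc - hc)^2)
    } else {
      num <- sum(yc[fin]^2); den <- sum((yc[fin] - hc[fin])^2)
    }
    snr_k <- if (den == 0) Inf else num / den
    if (is.null(best) || snr_k > best$q) {
      best <- list(q = snr_k, k = k, y = yc, y_hat = hc,
                   nan_frac = mean(!fin))
    }
  }
  list(shift_ms = best$k * 1000 / rate, y = best$y, y_hat = best$y_hat,
       nan_frac = best$nan_frac)
}

#' Signal-to-noise ratio in decibels
#'
#' `10 log10(sum(y^2) / sum((y - y_hat)^2))` on aligned, centred inputs.
#' Zero noise power gives `Inf`; zero signal power gives `NaN` with a
#' warning.
#'
#' @param y Centred ground truth.
#' @param y_hat Centred, aligned reconstruction (NA scored as 0).
#' @return SNR in dB.
#' @export
snr <- function(y, y_hat) {
  y_hat[is.na(y_hat)] <- 0
  sp <- sum(y^2)
  np <- sum((y - y_hat)^2)
  if (sp == 0) {
    warning("zero signal power: SNR undefined")
    return(NaN)
  }
  if (np == 0) return(Inf)
  10 * log10(sp / np)
}

#' Root-mean-square error in microvolts
#' @param y,y_hat Aligned series in mV (NA in `y_hat` scored as 0).
#' @return RMSE in microvolts.
#' @export
rmse <- function(y, y_hat) {
  y_hat[is.na(y_hat)] <- 0
  sqrt(mean((y - y_hat)^2)) * 1000
}

#' Pearson correlation of aligned series
#' @param y,y_hat Aligned series (NA in `y_hat` scored as 0).
#' @return Correlation in \[-1, 1\]; NA with a warning for constant input.
#' @export
trace_correlation <- function(y, y_hat) {
  y_hat[is.na(y_hat)] <- 0
  if (sd(y) == 0 || sd(y_hat) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(y, y_hat)
}

#' Evaluate a reconstructed record against a reference record
#'
#' Metrics are computed per lead on the shared leads, then aggregated as
#' mean and standard deviation; infinite SNR values (perfect
#' reconstructions) are excluded from the aggregates and counted.
#'
#' @param truth Reference `ecg_record` (or matrix with lead columns).
#' @param rec Reconstructed `ecg_record`, same rate.
#' @param max_shift_ms Alignment bound (default 100).
#' @param nan_mode See [align_signals()].
#' @param span `"full"` compares entire series; `"observed"` restricts each
#'   lead to the time span where the reconstruction has finite samples
#'   (appropriate when a layout prints each lead only for part of the
#'   record).
#' @return An `ecg_eval`: list with `per_lead` (data frame: lead, snr_db,
#'   rmse_uV, correlation, shift_ms, nan_frac) and `aggregate` (mean, sd,
#'   n_inf_snr).
#' @export
evaluate_record <- function(truth, rec, max_shift_ms = 100,
                            nan_mode = "zero", span = c("full", "observed")) {
  span <- match.arg(span)
  tm <- if (inherits(truth, "ecg_record")) truth$samples else truth
  rm_ <- if (inherits(rec, "ecg_record")) rec$samples else rec
  rate <- if (inherits(truth, "ecg_record")) truth$rate else 1000
  shared <- intersect(colnames(tm), colnames(rm_))
  if (!length(shared)) stop("no shared leads between truth and reconstruction")
  rows <- lapply(shared, function(lead) {
    y <- tm[, lead]
    yh <- rm_[, lead]
    if (span == "observed" && any(is.finite(yh))) {
      obs <- range(which(is.finite(yh)))
      y <- y[obs[1]:obs[2]]
      yh <- yh[obs[1]:obs[2]]
    }
    al <- align_signals(y, yh, max_shift_ms, rate, nan_mode)
    suppressWarnings(data.frame(
      lead = lead,
      snr_db = snr(al$y, al$y_hat),
      rmse_uV = rmse(al$y, al$y_hat),
      correlation = trace_correlation(al$y, al$y_hat),
      shift_ms = al$shift_ms,
      nan_frac = al$nan_frac, stringsAsFactors = FALSE))
  })
  per_lead <- do.call(rbind, rows)
  fin <- is.finite(per_lead$snr_db)
  agg <- data.frame(
    metric = c("snr_db", "rmse_uV", "correlation"),
    mean = c(mean(per_lead$snr_db[fin]), mean(per_lead$rmse_uV),
             mean(per_lead$correlation, na.rm = TRUE)),
    sd = c(sd(per_lead$snr_db[fin]), sd(per_lead$rmse_uV),
           sd(per_lead$correlation, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  structure(list(per_lead = per_lead, aggregate = agg,
                 n_inf_snr = sum(!fin & !is.nan(per_lead$snr_db))),
            class = "ecg_eval")
}

#' @export
print.ecg_eval <- function(x, ...) {
  cat("<ecg_eval>\n")
  print(x$per_lead, digits = 4)
  cat("aggregate:\n")
  print(x$aggregate, digits = 4)
  invisible(x)
}
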