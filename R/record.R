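# ECG record assembly and output writers (wide CSV and a minimal WFDB
# writer: text header + 16-bit little-endian signal file).

#' Assemble per-lead traces into a uniformly sampled record
#'
#' Each trace is resampled to the target rate by linear interpolation over
#' finite runs; NA gaps are preserved, never interpolated across. Leads are
#' placed at their layout time offsets; rhythm leads span the full record.
#'
#' @param traces Named list: for each lead, a list with `t` (sample times in
#'   seconds) and `mv` (values, NA allowed).
#' @param duration_s Record duration.
#' @param target_rate Output sample rate in Hz (default 1000).
#' @param gap_fill_ms NA runs no longer than this are bridged by linear
#'   interpolation before resampling (isolated pixel-column dropouts, not
#'   genuine failures); longer runs stay NA. Default 20 ms; 0 disables.
#' @param calibration Optional `calibration` stored as metadata.
#' @param layout_name Layout identifier stored as metadata.
#' @param warnings Character vector of pipeline warnings.
#' @return An `ecg_record`: list with `leads`, `samples` (time x lead matrix
#'   in mV, NA-capable), `rate`, `duration_s` and metadata.
#' @export
assemble_record <- function(traces, duration_s, target_rate = 1000,
                            calibration = NULL, layout_name = NA_character_,
                            warnings = character(), gap_fill_ms = 20) {
  if (target_rate <= 0) stop("target_rate must be > 0")
  n <- round(duration_s * target_rate)
  t_out <- (seq_len(n) - 1) / target_rate
  leads <- names(traces)
  samples <- matrix(NA_real_, n, length(leads),
                    dimnames = list(NULL, leads))
  for (lead in leads) {
    tr <- traces[[lead]]
    if (is.null(tr) || !length(tr$t)) next
    v <- fill_short_gaps(tr$t, tr$mv, gap_fill_ms / 1000)
    samples[, lead] <- resample_with_gaps(tr$t, v, t_out)
  }
  structure(list(leads = leads, samples = samples, rate = target_rate,
                 duration_s = duration_s, calibration = calibration,
                 layout_name = layout_name, warnings = warnings),
            class = "ecg_record")
}

# Bridge NA runs whose duration is at most max_gap_s by linear
# interpolation between their finite neighbours; longer runs are kept NA.
fill_short_gaps <- function(t_in, v_in, max_gap_s) {
  if (max_gap_s <= 0 || !anyNA(v_in) || sum(!is.na(v_in)) < 2) return(v_in)
  na_run <- rle(is.na(v_in))
  ends <- cumsum(na_run$lengths)
  starts <- ends - na_run$lengths + 1
  filled <- approx(t_in[!is.na(v_in)], v_in[!is.na(v_in)], xout = t_in,
                   rule = 1)$y
  for (k in which(na_run$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1 || i1 == length(v_in)) next # edges stay NA
    if (t_in[i1 + 1] - t_in[i0 - 1] <= max_gap_s) {
      v_in[i0:i1] <- filled[i0:i1]
    }
  }
  v_in
}

# Linear interpolation that refuses to bridge NA gaps: an output point is NA
# unless both bracketing input samples are finite.
resample_with_gaps <- function(t_in, v_in, t_out) {
  ord <- order(t_in)
  t_in <- t_in[ord]; v_in <- v_in[ord]
  out <- rep(NA_real_, length(t_out))
  if (!length(t_in)) return(out)
  i <- findInterval(t_out, t_in)
  inside <- i >= 1 & t_out <= t_in[length(t_in)] + 1e-12
  idx <- which(inside)
  ii <- pmin(i[idx], length(t_in))
  jj <- pmin(ii + 1, length(t_in))
  v0 <- v_in[ii]; v1 <- v_in[jj]
  dt <- t_in[jj] - t_in[ii]
  f <- ifelse(dt > 0, (t_out[idx] - t_in[ii]) / dt, 0)
  at_lo <- f <= 1e-6 # output point coincides with an input sample
  at_hi <- f >= 1 - 1e-6
  val <- ifelse(at_lo, v0, ifelse(at_hi, v1, v0 * (1 - f) + v1 * f))
  val[!at_lo & !at_hi & (is.na(v0) | is.na(v1))] <- NA
  out[idx] <- val
  out
}

#' Wrap a simulated signal as an `ecg_record`
#' @param signal A `multi_lead_signal`.
#' @return An `ecg_record` at the signal's native rate.
#' @export
signal_to_record <- function(signal) {
  structure(list(leads = signal$lead_names, samples = signal$samples,
                 rate = signal$rate,
                 duration_s = nrow(signal$samples) / signal$rate,
                 calibration = NULL, layout_name = NA_character_,
                 warnings = character()),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  nan_pct <- 100 * mean(is.na(x$samples))
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz (%.2f%% NA, layout %s)\n",
              length(x$leads), nrow(x$samples), x$rate, nan_pct,
              x$layout_name))
  invisible(x)
}

#' Write a record as a wide CSV (time_s + one column per lead)
#'
#' @param record An `ecg_record`.
#' @param path Output path. NA samples become empty cells.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  df <- data.frame(time_s = (seq_len(nrow(record$samples)) - 1) / record$rate,
                   record$samples, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a wide CSV written by [write_record_csv()]
#' @param path CSV path.
#' @return An `ecg_record`.
#' @export
read_record_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  rate <- 1 / median(diff(df$time_s))
  m <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  structure(list(leads = colnames(m), samples = m, rate = rate,
                 duration_s = nrow(m) / rate, calibration = NULL,
                 layout_name = NA_character_, warnings = character()),
            class = "ecg_record")
}

WFDB_INVALID <- -32768L

#' Write a record in WFDB format (16-bit signal file + header)
#'
#' Uses format 16 (interleaved little-endian int16) with a fixed gain of
#' 200 adu/mV; NA samples are stored as the WFDB invalid-sample sentinel.
#'
#' @param record An `ecg_record`.
#' @param prefix Path prefix; writes `<prefix>.hea` and `<prefix>.dat`.
#' @return `prefix`, invisibly.
#' @export
write_record_wfdb <- function(record, prefix) {
  gain <- 200
  n <- nrow(record$samples)
  nsig <- ncol(record$samples)
  adc <- round(record$samples * gain)
  adc[is.na(adc)] <- WFDB_INVALID
  adc <- pmax(pmin(adc, 32767), -32768)
  rec_name <- basename(prefix)
  hdr <- c(sprintf("%s %d %g %d", rec_name, nsig, record$rate, n))
  for (j in seq_len(nsig)) {
    checksum <- sum(adc[, j]) %% 65536
    if (checksum >= 32768) checksum <- checksum - 65536
    hdr <- c(hdr, sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s", rec_name,
                          gain, as.integer(adc[1, j]), as.integer(checksum),
                          record$leads[j]))
  }
  writeLines(hdr, paste0(prefix, ".hea"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(prefix)
}

#' Read a WFDB record written by [write_record_wfdb()]
#' @param prefix Path prefix (without extension).
#' @return An `ecg_record` (invalid samples become NA).
#' @export
read_record_wfdb <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".hea"))
  top <- strsplit(hdr[1], " +")[[1]]
  nsig <- as.integer(top[2]); rate <- as.numeric(top[3]); n <- as.integer(top[4])
  leads <- vapply(hdr[1 + seq_len(nsig)], function(l) {
    parts <- strsplit(l, " +")[[1]]
    parts[length(parts)]
  }, "", USE.NAMES = FALSE)
  gains <- vapply(hdr[1 + seq_len(nsig)], function(l) {
    as.numeric(sub("\\(.*", "", strsplit(l, " +")[[1]][3]))
  }, 0, USE.NAMES = FALSE)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  raw_v <- readBin(con, "integer", n = n * nsig, size = 2, endian = "little",
                   signed = TRUE)
  m <- matrix(raw_v, n, nsig, byrow = TRUE)
  out <- m / rep(gains, each = n)
  out[m == WFDB_INVALID] <- NA
  colnames(out) <- leads
  structure(list(leads = leads, samples = out, rate = rate,
                 duration_s = n / rate, calibration = NULL,
                 layout_name = NA_character_, warnings = character()),
            class = "ecg_record")
}
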