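# Pre-processing: zero-phase band-pass, fixed-length windowing, per-window
# artifact rejection, and the minimum-usable-signal gate.

#' Zero-phase band-pass filter an EEG record
#'
#' Subtracts the signal mean, then applies an order-`order` Butterworth
#' band-pass forward and backward (`signal::filtfilt`), so slow waves are
#' not phase-shifted. The default 0.5–20 Hz band keeps delta through beta
#' activity and removes DC drift and most EMG.
#'
#' @param record An [eeg_record()].
#' @param low_cut,high_cut Band edges, Hz. Must satisfy
#'   `0 < low_cut < high_cut < sampling_rate / 2`.
#' @param order Butterworth design order.
#' @return A filtered [eeg_record()] of identical length and sampling rate.
#' @export
bandpass_filter <- function(record, low_cut = 0.5, high_cut = 20, order = 4) {
  stopifnot(inherits(record, "eeg_record"))
  if (length(record$samples) == 0L) stop("cannot filter an empty record")
  nyq <- record$sampling_rate / 2
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < nyq)) {
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz",
                 low_cut, high_cut, nyq))
  }
  bf <- signal::butter(order, c(low_cut, high_cut) / nyq, type = "pass")
  x <- record$samples - mean(record$samples)
  record$samples <- as.numeric(signal::filtfilt(bf, x))
  record
}

#' Cut a record into fixed-duration non-overlapping windows
#'
#' Windows are aligned to the record start; a trailing segment shorter than
#' one window is dropped. A record shorter than one window yields an empty
#' window set, not an error.
#'
#' @param record An [eeg_record()].
#' @param duration Window length in seconds; `duration * sampling_rate`
#'   must be a whole number of samples.
#' @return A `window_set`: samples matrix (one column per window), window
#'   start indices (0-based samples), per-window QC status and reason.
#' @export
segment_windows <- function(record, duration) {
  stopifnot(inherits(record, "eeg_record"), duration > 0)
  npw <- duration * record$sampling_rate
  if (abs(npw - round(npw)) > 1e-9) {
    stop("window duration must be a whole number of samples")
  }
  npw <- as.integer(round(npw))
  k <- length(record$samples) %/% npw
  samples <- if (k > 0L) {
    matrix(record$samples[seq_len(k * npw)], nrow = npw, ncol = k)
  } else {
    matrix(numeric(0), nrow = npw, ncol = 0L)
  }
  structure(
    list(samples = samples,
         start_index = (seq_len(k) - 1L) * npw,
         duration = duration,
         sampling_rate = record$sampling_rate,
         qc_status = rep("pending", k),
         qc_reason = rep(NA_character_, k)),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %g s at %g Hz (%d passed, %d rejected, %d pending)\n",
              ncol(x$samples), x$duration, x$sampling_rate,
              sum(x$qc_status == "passed"), sum(x$qc_status == "rejected"),
              sum(x$qc_status == "pending")))
  invisible(x)
}

#' Per-window artifact rejection
#'
#' A window passes QC iff its peak absolute amplitude is at most
#' `max_abs_amplitude_uv`, its variance is at least `min_variance`
#' (otherwise it is a flatline), and at most `max_high_band_fraction` of
#' its post-filter power lies above `high_band_hz`. Rejections record which
#' rule fired (`amplitude`, `flatline`, `high_freq_power`); the checks are
#' applied in that order. The predicate is deterministic and each window is
#' judged independently.
#'
#' @param windows A `window_set` from [segment_windows()], already
#'   band-pass filtered.
#' @param thresholds List with elements `max_abs_amplitude_uv` (µV),
#'   `min_variance` (µV²), `max_high_band_fraction` (0–1] and
#'   `high_band_hz` (Hz); see [bseeg_config()].
#' @return The window set with `qc_status`/`qc_reason` filled in.
#' @export
qc_windows <- function(windows, thresholds = bseeg_config()$qc) {
  stopifnot(inherits(windows, "window_set"))
  th <- thresholds
  for (j in seq_len(ncol(windows$samples))) {
    w <- windows$samples[, j]
    if (max(abs(w)) > th$max_abs_amplitude_uv) {
      windows$qc_status[j] <- "rejected"; windows$qc_reason[j] <- "amplitude"
    } else if (stats::var(w) < th$min_variance) {
      windows$qc_status[j] <- "rejected"; windows$qc_reason[j] <- "flatline"
    } else {
      ps <- periodogram(w, windows$sampling_rate)
      tot <- sum(ps$density)
      frac <- if (tot > 0) sum(ps$density[ps$frequency > th$high_band_hz]) / tot else 0
      if (frac > th$max_high_band_fraction) {
        windows$qc_status[j] <- "rejected"
        windows$qc_reason[j] <- "high_freq_power"
      } else {
        windows$qc_status[j] <- "passed"
      }
    }
  }
  windows
}

#' Minimum-usable-signal gate
#'
#' A subject-channel enters scoring only if its QC-passed windows cover at
#' least `min_seconds` of signal (default 30 s; the boundary case of
#' exactly 30 s counts as usable).
#'
#' @param windows A `window_set` after [qc_windows()].
#' @param min_seconds Required seconds of passed signal.
#' @return Logical scalar.
#' @export
usable <- function(windows, min_seconds = 30) {
  stopifnot(inherits(windows, "window_set"))
  sum(windows$qc_status == "passed") * windows$duration >= min_seconds
}

#' Integer-factor decimation
#'
#' Keeps every `factor`-th sample of an already low-passed record. Used to
#' bring 500 Hz recordings to 125 Hz before delay embedding so point-cloud
#' sizes are comparable across devices; the 0.5–20 Hz band-pass that
#' precedes it leaves no energy near the new 62.5 Hz Nyquist, so no extra
#' anti-alias filter is needed.
#'
#' @param record A filtered [eeg_record()].
#' @param factor Positive integer decimation factor.
#' @return The decimated [eeg_record()].
#' @export
decimate_record <- function(record, factor) {
  stopifnot(inherits(record, "eeg_record"),
            factor == round(factor), factor >= 1)
  if (factor == 1) return(record)
  record$samples <- record$samples[seq(1L, length(record$samples), by = factor)]
  record$sampling_rate <- record$sampling_rate / factor
  record
}
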