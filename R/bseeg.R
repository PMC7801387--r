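# The spectral-slowing (BSEEG) score: log10 of the ratio of power spectral
# density at 3 Hz to that at 10 Hz, per 4-s window, aggregated per
# subject-channel. Positive scores mean slow (delta/theta) activity
# dominates the alpha band — the diffuse-slowing EEG signature of delirium.

#' One-sided FFT periodogram
#'
#' Density scaling is Parseval-consistent: `sum(density) * df` equals the
#' mean square of the (de-meaned) input, with `df = 1/duration` — 0.25 Hz
#' for a 4-s window at either 500 Hz or 128 Hz, so 3 Hz and 10 Hz are exact
#' grid frequencies.
#'
#' @param x Numeric vector of samples (µV), or a 1-column piece of a
#'   window set.
#' @param sampling_rate Hz.
#' @param taper `"rectangular"` (default; target frequencies are exact
#'   bins) or `"hann"`.
#' @return A `power_spectrum`: list with `frequency` (Hz) and `density`
#'   (µV²/Hz) vectors.
#' @export
periodogram <- function(x, sampling_rate, taper = "rectangular") {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 2L, sampling_rate > 0)
  if (identical(taper, "hann")) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    x <- x * w / sqrt(mean(w^2))  # power-normalized taper
  } else if (!identical(taper, "rectangular")) {
    stop("unknown taper: ", taper)
  }
  xf <- stats::fft(x)
  half <- floor(n / 2)
  idx <- seq_len(half + 1L)           # DC .. Nyquist (or near-Nyquist)
  dens <- Mod(xf[idx])^2 / (sampling_rate * n)
  two_sided <- idx > 1L & idx < (n / 2 + 1L)
  dens[two_sided] <- 2 * dens[two_sided]
  structure(
    list(frequency = (idx - 1L) * sampling_rate / n, density = dens),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0-%g Hz (df = %g Hz)\n",
              length(x$frequency), max(x$frequency), x$frequency[2]))
  invisible(x)
}

# PSD read-off at a target frequency: nearest grid bin, or the mean of the
# bins within +/- 0.25 Hz when band averaging is requested
.psd_at <- function(spectrum, hz, band_average = FALSE) {
  if (band_average) {
    sel <- abs(spectrum$frequency - hz) <= 0.25 + 1e-9
    mean(spectrum$density[sel])
  } else {
    spectrum$density[which.min(abs(spectrum$frequency - hz))]
  }
}

#' Spectral-slowing score of a single window
#'
#' `log10(PSD(low_hz) / PSD(high_hz))` with defaults low = 3 Hz,
#' high = 10 Hz: positive when slowing dominates, negative for a normal
#' alpha-dominant spectrum, and invariant to amplitude scaling. With
#' `log10 = FALSE` the raw ratio is returned. A zero denominator is floored
#' at `1e-6` times the smallest positive density so the score is never
#' infinite; an all-zero spectrum gives `NA` (such windows are rejected as
#' flatlines upstream).
#'
#' @param x Samples of one QC-passed window (µV).
#' @param sampling_rate Hz.
#' @param params The `bseeg` element of [bseeg_config()].
#' @return Numeric score.
#' @export
bseeg_window_score <- function(x, sampling_rate, params = bseeg_config()$bseeg) {
  ps <- periodogram(x, sampling_rate, taper = params$taper)
  lo <- .psd_at(ps, params$low_hz, params$band_average)
  hi <- .psd_at(ps, params$high_hz, params$band_average)
  pos <- ps$density[ps$density > 0]
  if (!length(pos)) return(NA_real_)
  eps <- min(pos) * 1e-6
  ratio <- max(lo, eps) / max(hi, eps)
  if (isTRUE(params$log10)) log10(ratio) else ratio
}

#' Aggregate per-window scores into a subject-channel score
#'
#' The median (default) is robust to residual artifact windows; the mean is
#' available via `params$aggregate = "mean"`.
#'
#' @param window_scores Numeric vector of per-window scores.
#' @param params List with an `aggregate` element.
#' @return Numeric scalar, or `NA` (with a warning) for empty input.
#' @export
aggregate_bseeg <- function(window_scores, params = bseeg_config()$bseeg) {
  window_scores <- window_scores[!is.na(window_scores)]
  if (!length(window_scores)) {
    warning("no usable windows: score is missing")
    return(NA_real_)
  }
  switch(params$aggregate,
         median = stats::median(window_scores),
         mean = mean(window_scores),
         stop("unknown aggregate: ", params$aggregate))
}
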