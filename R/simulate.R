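# Synthetic forehead EEG with the structure the scores assume: an
# alpha-dominant (~10 Hz) normal rhythm versus delta/theta-dominant
# diffuse slowing, on a 1/f background, with optional EMG-burst, ECG-spike,
# baseline-drift and flatline artifacts. The generator exists to exercise
# the pipeline end to end without patient data; it is not a neural-mass
# model.

# evaluate `expr` under `seed` without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# smooth unit-range noise: spline through ~2 control points per second
.smooth_noise <- function(n, fs, per_second = 2) {
  k <- max(4L, ceiling(n / fs * per_second))
  ctrl <- stats::rnorm(k)
  w <- stats::spline(seq(0, 1, length.out = k), ctrl, n = n)$y
  m <- max(abs(w))
  if (m > 0) w / m else w
}

# narrow-band oscillation with wandering frequency and slow amplitude
# modulation; f_dev sets the half-width of the frequency wander (Hz).
# The wander is a ~0.4 Hz sweep plus noise, so every analysis window sees
# the oscillation cross its whole band rather than parking off-bin.
.fm_oscillation <- function(n, fs, f0, f_dev, amplitude, mod_depth = 0.3) {
  tt <- (seq_len(n) - 1L) / fs
  sweep <- sin(2 * pi * 0.4 * tt + stats::runif(1, 0, 2 * pi))
  f_inst <- f0 + f_dev * (0.75 * sweep + 0.25 * .smooth_noise(n, fs))
  phase <- cumsum(2 * pi * f_inst / fs) + stats::runif(1, 0, 2 * pi)
  env <- pmax(1 + mod_depth * .smooth_noise(n, fs), 0.2)
  amplitude * env * sin(phase)
}

# 1/f ("pink") background via FFT spectral shaping, scaled to a target RMS
.pink_noise <- function(n, fs, rms, f_floor = 0.5) {
  if (rms <= 0) return(numeric(n))
  xf <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  xf <- xf / sqrt(pmax(f, f_floor))
  xf[1] <- 0
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  x / stats::sd(x) * rms
}

.artifact_kinds <- c("emg", "ecg", "drift", "flatline")

# add one artifact in place; `at` is the onset in seconds
.add_artifact <- function(x, fs, kind, at, amplitude, duration) {
  n <- length(x)
  i0 <- max(1L, min(n, floor(at * fs) + 1L))
  switch(kind,
    emg = {
      m <- min(n - i0 + 1L, round(duration * fs))
      if (m > 8L) {
        # 15-30 Hz: overlaps the EEG pass-band enough that the burst's
        # post-filter remnant still dominates a window's high-band power
        nyq <- fs / 2
        bf <- signal::butter(4, c(15, min(30, 0.9 * nyq)) / nyq, type = "pass")
        burst <- as.numeric(signal::filtfilt(bf, stats::rnorm(m)))
        taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
        burst <- burst * taper
        burst <- burst / max(abs(burst)) * amplitude  # delivered peak
        x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] + burst
      }
    },
    ecg = {
      # ~1 Hz train of biphasic 80 ms spikes
      m <- round(0.08 * fs)
      beat <- amplitude * sin(2 * pi * seq_len(m) / m)
      for (b in 0:(max(1, round(duration)) - 1)) {
        j0 <- i0 + round(b * fs)
        j1 <- min(n, j0 + m - 1L)
        if (j0 <= n) x[j0:j1] <- x[j0:j1] + beat[seq_len(j1 - j0 + 1L)]
      }
    },
    drift = {
      m <- min(n - i0 + 1L, round(duration * fs))
      if (m > 2L) {
        tt <- seq_len(m) / fs
        taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
        x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] +
          amplitude * sin(2 * pi * 0.15 * tt) * taper
      }
    },
    flatline = {
      m <- min(n - i0 + 1L, round(duration * fs))
      x[i0:(i0 + m - 1L)] <- 0
    },
    stop("unknown artifact kind: ", kind)
  )
  x
}

#' Simulate a forehead EEG recording
#'
#' The clean signal is `(1 - slowing) * alpha + slowing * delta + pink
#' noise`: both oscillations wander in frequency (alpha ±0.8 Hz around
#' `alpha_freq`, delta ±1 Hz around `delta_freq`, so the slowing power
#' straddles the 3 Hz analysis bin rather than sitting on it) and are
#' slowly amplitude-modulated. Artifacts are then injected at Poisson
#' per-minute rates. Everything is deterministic given `seed`.
#'
#' @param sampling_rate Hz (the studied devices record at 500 or 128 Hz).
#' @param duration Seconds.
#' @param slowing Slowing index in `[0, 1]`: 0 = normal alpha-dominant,
#'   1 = fully slowed (delirium-like).
#' @param alpha_freq,delta_freq Center frequencies, Hz.
#' @param base_amplitude Oscillation amplitude scale, µV.
#' @param pink_noise_level RMS of the 1/f background, µV.
#' @param artifact_rates Named per-minute rates for `emg`, `ecg`, `drift`,
#'   `flatline` artifacts.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param subject_id,channel Metadata for the returned record.
#' @return An [eeg_record()] with the generation parameters attached as
#'   attribute `"sim_config"`.
#' @export
simulate_eeg <- function(sampling_rate = 128, duration = 120, slowing = 0,
                         alpha_freq = 10, delta_freq = 2.5,
                         base_amplitude = 30, pink_noise_level = 10,
                         artifact_rates = c(emg = 1, ecg = 4, drift = 0.5,
                                            flatline = 0),
                         seed = 1, subject_id = "sim", channel = "Fp1-A1") {
  stopifnot(slowing >= 0, slowing <= 1, duration > 0,
            base_amplitude >= 0, pink_noise_level >= 0)
  rates <- c(emg = 0, ecg = 0, drift = 0, flatline = 0)
  rates[names(artifact_rates)] <- artifact_rates
  n <- round(duration * sampling_rate)
  x <- .with_seed(seed, {
    x <- (1 - slowing) *
      .fm_oscillation(n, sampling_rate, alpha_freq, 0.8, base_amplitude) +
      slowing *
      .fm_oscillation(n, sampling_rate, delta_freq, 1.0, base_amplitude) +
      .pink_noise(n, sampling_rate, pink_noise_level)
    for (kind in .artifact_kinds) {
      n_events <- stats::rpois(1, rates[[kind]] * duration / 60)
      for (ev in seq_len(n_events)) {
        x <- .add_artifact(
          x, sampling_rate, kind,
          at = stats::runif(1, 0, max(0, duration - 2)),
          amplitude = switch(kind, emg = 5 * base_amplitude,
                             ecg = 2 * base_amplitude, drift = 4 * base_amplitude,
                             flatline = 0),
          duration = switch(kind, emg = stats::runif(1, 0.5, 2), ecg = 3,
                            drift = stats::runif(1, 5, 15), flatline = 5))
      }
    }
    x
  })
  rec <- eeg_record(x, sampling_rate, subject_id = subject_id,
                    channel = channel,
                    device = sprintf("synthetic-%gHz", sampling_rate))
  attr(rec, "sim_config") <- list(
    sampling_rate = sampling_rate, duration = duration, slowing = slowing,
    alpha_freq = alpha_freq, delta_freq = delta_freq,
    base_amplitude = base_amplitude, pink_noise_level = pink_noise_level,
    artifact_rates = rates, seed = seed)
  rec
}

#' Inject one artifact into a record
#'
#' Artifact shapes: `emg` — a 15–45 Hz noise burst of `duration` seconds
#' (default drawn from 0.5–2 s) at peak `amplitude`; `ecg` — a ~1 Hz train
#' of biphasic 80 ms spikes; `drift` — a sub-0.3 Hz high-amplitude swell;
#' `flatline` — a zeroed span. Position (and any unset shape parameter) is
#' drawn under `seed`.
#'
#' @param record An [eeg_record()].
#' @param kind One of `"emg"`, `"ecg"`, `"drift"`, `"flatline"`.
#' @param seed Integer seed.
#' @param amplitude Peak amplitude, µV (ignored for flatline).
#' @param duration Artifact span, seconds.
#' @param at Onset in seconds; `NULL` draws it uniformly.
#' @return The modified [eeg_record()].
#' @export
inject_artifact <- function(record, kind, seed = 1, amplitude = NULL,
                            duration = NULL, at = NULL) {
  stopifnot(inherits(record, "eeg_record"), length(record$samples) > 0)
  if (!kind %in% .artifact_kinds) stop("unknown artifact kind: ", kind)
  total <- length(record$samples) / record$sampling_rate
  record$samples <- .with_seed(seed, {
    if (is.null(at)) at <- stats::runif(1, 0, max(0, total - 2))
    if (is.null(duration)) {
      duration <- switch(kind, emg = stats::runif(1, 0.5, 2), ecg = 3,
                         drift = stats::runif(1, 5, 15), flatline = 5)
    }
    if (is.null(amplitude)) amplitude <- switch(kind, emg = 150, ecg = 60,
                                                drift = 120, flatline = 0)
    .add_artifact(record$samples, record$sampling_rate, kind, at, amplitude,
                  duration)
  })
  record
}

#' Simulate a labeled two-group cohort
#'
#' Each subject's slowing index is drawn Normal(group mean, sd = 0.08) and
#' clipped to `[0, 1]`; each recording gets its own derived seed. The
#' returned table is ready for [score_cohort()] + [evaluate_cohort()].
#'
#' @param n_delirious,n_control Group sizes (>= 1).
#' @param s_delirious,s_control Group-mean slowing indices.
#' @param seed Integer seed governing the whole cohort.
#' @param sampling_rate,duration,artifact_rates Passed to [simulate_eeg()].
#' @return List with `records` (list of [eeg_record()]) and `cohort`
#'   (data frame: `subject_id`, `delirium_label`, `slowing`).
#' @export
simulate_cohort <- function(n_delirious, n_control, s_delirious = 0.9,
                            s_control = 0.1, seed = 1, sampling_rate = 128,
                            duration = 120,
                            artifact_rates = c(emg = 1, ecg = 4, drift = 0.5,
                                               flatline = 0)) {
  stopifnot(n_delirious >= 1, n_control >= 1)
  n <- n_delirious + n_control
  draws <- .with_seed(seed, {
    list(s = pmin(1, pmax(0, stats::rnorm(
           n, rep(c(s_delirious, s_control), c(n_delirious, n_control)),
           0.08))),
         seeds = sample.int(2^30, n))
  })
  ids <- c(sprintf("D%03d", seq_len(n_delirious)),
           sprintf("C%03d", seq_len(n_control)))
  records <- lapply(seq_len(n), function(i) {
    simulate_eeg(sampling_rate = sampling_rate, duration = duration,
                 slowing = draws$s[i], artifact_rates = artifact_rates,
                 seed = draws$seeds[i], subject_id = ids[i])
  })
  list(records = records,
       cohort = data.frame(
         subject_id = ids,
         delirium_label = rep(c(1L, 0L), c(n_delirious, n_control)),
         slowing = draws$s))
}
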