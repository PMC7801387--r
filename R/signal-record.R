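#' Construct an EEG signal record
#'
#' A single subject-channel EEG trace with its device metadata. Amplitudes
#' are microvolts throughout the package; QC thresholds and artifact
#' amplitudes are stated on that scale.
#'
#' @param samples Numeric vector of amplitudes (µV). All values must be
#'   finite.
#' @param sampling_rate Samples per second (Hz), positive.
#' @param subject_id Subject identifier.
#' @param channel Channel label, canonically `"Fp1-A1"` or `"Fp2-A2"`.
#' @param device Free-text device tag (e.g. `"CMS2100-500Hz"`, `"ZA-128Hz"`).
#'
#' @return An object of class `eeg_record`: a list with fields
#'   `subject_id`, `channel`, `sampling_rate`, `samples`, `device`.
#' @examples
#' rec <- eeg_record(sin(2 * pi * 10 * seq(0, 2, by = 1 / 128)), 128)
#' duration(rec)
#' @export
eeg_record <- function(samples, sampling_rate, subject_id = "anonymous",
                       channel = "Fp1-A1", device = "unknown") {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)")
  }
  if (length(samples) && !all(is.finite(samples))) {
    stop("all amplitudes must be finite")
  }
  structure(
    list(subject_id = as.character(subject_id),
         channel = as.character(channel),
         sampling_rate = as.numeric(sampling_rate),
         samples = samples,
         device = as.character(device)),
    class = "eeg_record"
  )
}

#' @rdname eeg_record
#' @param x,record An `eeg_record`.
#' @export
duration <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  length(record$samples) / record$sampling_rate
}

#' @rdname eeg_record
#' @param ... Ignored.
#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> subject %s, channel %s, %g Hz, %.1f s (%d samples), device %s\n",
              x$subject_id, x$channel, x$sampling_rate,
              duration(x), length(x$samples), x$device))
  invisible(x)
}

# canonical channel matching: case-insensitive, separator-tolerant
.canonical_label <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Match device channel labels against the forehead montage
#'
#' EDF label conventions vary by device; matching is case-insensitive and
#' ignores separators, so `"FP1A1"`, `"Fp1_A1"` and `"fp1-a1"` all map to
#' `"Fp1-A1"`. The alias map can be extended for unusual exports.
#'
#' @param labels Character vector of labels found in a file.
#' @param aliases Named list mapping canonical channel names to accepted
#'   label variants.
#' @return Character vector of the same length: the canonical channel name,
#'   or `NA` where a label matches no alias.
#' @export
match_channel <- function(labels,
                          aliases = list(
                            "Fp1-A1" = c("Fp1-A1", "FP1A1", "Fp1_A1", "EEG Fp1-A1"),
                            "Fp2-A2" = c("Fp2-A2", "FP2A2", "Fp2_A2", "EEG Fp2-A2"))) {
  canon <- lapply(aliases, .canonical_label)
  vapply(labels, function(lab) {
    key <- .canonical_label(lab)
    hit <- names(canon)[vapply(canon, function(a) key %in% a, logical(1))]
    if (length(hit)) hit[[1L]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}
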