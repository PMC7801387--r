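# Minimal EDF/EDF+ support: continuous recordings, 16-bit samples,
# physical scaling from the signal headers. Covers what a two-channel
# forehead montage needs; annotations, discontinuous records and BDF are
# out of scope.

.edf_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = -width)  # left-justified, space padded
}

# shortest decimal representation of `x` that fits an 8-char header field
.edf_num8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, digits = digits, format = "g", flag = "-")
    s <- sub("\\s+$", "", s)
    if (nchar(s) <= 8L) return(s)
  }
  stop("cannot represent ", x, " in an 8-character EDF field")
}

#' Write EEG records to an EDF file
#'
#' Encodes each record as one EDF signal with 16-bit samples, a symmetric
#' physical range chosen from the data, and one-second data records. The
#' trailing partial second (if any) is dropped, since EDF stores whole data
#' records only. All records must share one sampling rate, which must be a
#' whole number of samples per second.
#'
#' @param records A list of [eeg_record()] objects (or a single record).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(records, path) {
  if (inherits(records, "eeg_record")) records <- list(records)
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "eeg_record")))
  fs <- unique(vapply(records, `[[`, numeric(1), "sampling_rate"))
  if (length(fs) != 1L || fs != round(fs)) {
    stop("all records must share one integer sampling rate")
  }
  n_rec <- min(vapply(records, function(r) length(r$samples) %/% fs, numeric(1)))
  if (n_rec < 1L) stop("records shorter than one second cannot be stored as EDF")
  ns <- length(records)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(x, width) writeChar(.edf_field(x, width), con, nchars = width,
                                     eos = NULL)
  # fixed header (256 bytes)
  wr("0", 8)
  wr(records[[1L]]$subject_id, 80)
  wr(paste("Startdate 01.JAN.2020", records[[1L]]$device), 80)
  wr("01.01.20", 8)
  wr("00.00.00", 8)
  wr(256L * (1L + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)  # record duration, seconds
  wr(ns, 4)

  amax <- vapply(records, function(r) {
    m <- max(abs(r$samples), 1e-6)
    as.numeric(.edf_num8(m * 1.000001))  # headroom so no sample clips
  }, numeric(1))

  for (r in records) wr(r$channel, 16)
  for (r in records) wr("forehead electrode", 80)
  for (r in records) wr("uV", 8)
  for (i in seq_len(ns)) wr(.edf_num8(-amax[i]), 8)
  for (i in seq_len(ns)) wr(.edf_num8(amax[i]), 8)
  for (i in seq_len(ns)) wr("-32767", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (r in records) wr("HP:0.0Hz LP:none", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (rec in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- records[[i]]$samples[((rec - 1L) * fs + 1L):(rec * fs)]
      dig <- as.integer(round(seg / amax[i] * 32767))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read forehead-montage channels from an EDF file
#'
#' Parses the EDF header, converts samples to physical units using each
#' signal's physical/digital ranges, rescales to microvolts from the
#' physical-dimension field (`uV`, `mV` or `V`), and returns one
#' [eeg_record()] per channel whose label matches the forehead montage.
#' The sampling rate is taken from the file header; no resampling is done.
#'
#' @param path Path to an EDF/EDF+ file.
#' @param aliases Channel alias map, see [match_channel()].
#' @return A list of [eeg_record()] objects, one per matched channel.
#' @export
read_edf <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) {
    out <- readChar(con, width, useBytes = TRUE)
    if (nchar(out, type = "bytes") < width) stop("corrupt EDF header in ", path)
    trimws(out)
  }
  rd(8)                      # version
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)               # start date/time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop("corrupt EDF header in ", path)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  vapply(seq_len(ns), function(i) rd(80), character(1))   # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(80), character(1))    # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  vapply(seq_len(ns), function(i) rd(32), character(1))    # reserved
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    stop("corrupt EDF signal headers in ", path)
  }
  seek(con, header_bytes)

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(0)
  for (rec in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2L,
                      signed = TRUE, endian = "little")
      if (length(vals) < spr[i]) stop("truncated EDF data in ", path)
      raw[[i]][((rec - 1L) * spr[i] + 1L):(rec * spr[i])] <- vals
    }
  }

  matched <- if (is.null(aliases)) match_channel(labels) else
    match_channel(labels, aliases)
  if (all(is.na(matched))) {
    stop("channel not found: no label matches the forehead montage; ",
         "available labels: ", paste(labels, collapse = ", "))
  }
  to_uv <- list(uv = 1, "µv" = 1, mv = 1e3, v = 1e6)
  out <- list()
  for (i in which(!is.na(matched))) {
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys <- (raw[[i]] - dig_min[i]) * gain + phys_min[i]
    key <- tolower(dims[i])
    scale <- if (key %in% names(to_uv)) to_uv[[key]] else 1
    out[[length(out) + 1L]] <- eeg_record(
      phys * scale, sampling_rate = spr[i] / rec_dur,
      subject_id = patient, channel = matched[i], device = recording)
  }
  out
}
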