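# Plain-text signal and score-table dialects.
#
# Signal CSV: header `time_s,<channel>[,<channel>]`, one sample per row,
# "." decimal, UTF-8. Score CSV: header
# `subject_id,channel,delirium_label,bseeg_score,tda_score,
#  n_windows_total,n_windows_passed`; missing values are empty cells
# (never the text "NA"/"NaN"); delirium_label is 0, 1 or empty.

#' Read EEG signals from a CSV file
#'
#' One [eeg_record()] is returned per signal column. The sampling rate is
#' taken from the `sampling_rate` argument when given, otherwise inferred
#' from the spacing of the `time_s` column. The reader never resamples.
#'
#' @param path Path to a signal CSV (dialect above).
#' @param sampling_rate Sampling rate in Hz; `NULL` to infer from `time_s`.
#' @param subject_id,device Metadata attached to the returned records.
#' @return List of [eeg_record()] objects.
#' @export
read_csv_signal <- function(path, sampling_rate = NULL,
                            subject_id = "anonymous", device = "csv") {
  if (!file.exists(path)) stop("cannot read signal CSV: ", path)
  txt <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(txt) == 0L || ncol(txt) < 2L || names(txt)[1L] != "time_s") {
    stop("signal CSV format error: expected header `time_s,<channel>[,...]` in ",
         path)
  }
  num <- lapply(txt, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !(txt[[j]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("non-numeric cell in column `%s`, row %d of %s: \"%s\"",
                   names(txt)[j], bad[1L], path, txt[[j]][bad[1L]]))
    }
  }
  if (is.null(sampling_rate)) {
    dt <- diff(num[[1L]])
    if (length(dt) < 1L || any(dt <= 0)) {
      stop("cannot infer sampling rate from time_s in ", path)
    }
    sampling_rate <- 1 / stats::median(dt)
  }
  lapply(names(txt)[-1L], function(ch) {
    eeg_record(num[[ch]], sampling_rate, subject_id = subject_id,
               channel = ch, device = device)
  })
}

#' Write EEG signals to a CSV file
#'
#' Samples are written with full double precision (`%.17g`) so a read-back
#' reproduces them exactly.
#'
#' @param records A list of [eeg_record()] objects sharing one sampling rate
#'   and length (or a single record).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_signal <- function(records, path) {
  if (inherits(records, "eeg_record")) records <- list(records)
  stopifnot(length(records) >= 1L)
  fs <- records[[1L]]$sampling_rate
  n <- length(records[[1L]]$samples)
  for (r in records) {
    stopifnot(inherits(r, "eeg_record"), r$sampling_rate == fs,
              length(r$samples) == n)
  }
  cols <- c(list(time_s = sprintf("%.17g", (seq_len(n) - 1L) / fs)),
            stats::setNames(
              lapply(records, function(r) sprintf("%.17g", r$samples)),
              vapply(records, `[[`, character(1), "channel")))
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

.score_cols <- c("subject_id", "channel", "delirium_label", "bseeg_score",
                 "tda_score", "n_windows_total", "n_windows_passed")

#' Read and write subject score tables
#'
#' The score table holds one row per subject-channel with the aggregated
#' BSEEG and TDA scores and window-count bookkeeping. A score is missing
#' (empty cell) exactly when the usable-signal gate failed for that
#' subject-channel; `delirium_label` may be missing when no clinical
#' assessment is attached.
#'
#' @param scores A data frame with (at least) the columns
#'   `subject_id, channel, delirium_label, bseeg_score, tda_score,
#'   n_windows_total, n_windows_passed`.
#' @param path File path.
#' @return `read_scores()` returns the table as a data frame;
#'   `write_scores()` returns `path` invisibly.
#' @export
write_scores <- function(scores, path) {
  missing_cols <- setdiff(.score_cols, names(scores))
  if (length(missing_cols)) {
    stop("score table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(scores) &&
      any(scores$n_windows_passed > scores$n_windows_total, na.rm = TRUE)) {
    stop("n_windows_passed must not exceed n_windows_total")
  }
  out <- scores[, .score_cols, drop = FALSE]
  fmt <- function(x, f) ifelse(is.na(x), "", f(x))
  out$delirium_label <- fmt(out$delirium_label, function(v) as.integer(v))
  out$bseeg_score <- fmt(out$bseeg_score, function(v) sprintf("%.17g", v))
  out$tda_score <- fmt(out$tda_score, function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("cannot read score table: ", path)
  df <- utils::read.csv(path, colClasses = "character", na.strings = "")
  if (!identical(names(df), .score_cols)) {
    stop("score CSV format error: expected header ",
         paste(.score_cols, collapse = ","), " in ", path)
  }
  df$delirium_label <- as.integer(df$delirium_label)
  df$bseeg_score <- as.numeric(df$bseeg_score)
  df$tda_score <- as.numeric(df$tda_score)
  df$n_windows_total <- as.integer(df$n_windows_total)
  df$n_windows_passed <- as.integer(df$n_windows_passed)
  df
}
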