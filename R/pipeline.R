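# Stage composition: raw record -> band-pass -> windowing (4 s for the
# spectral score, 2 s for the topological score) -> per-window QC ->
# usable-signal gate -> per-window scores -> per-subject aggregates; then
# cohort-level ROC evaluation of the score table.

#' Score one subject-channel record
#'
#' Runs the full per-subject pipeline. The 4-s (BSEEG) and 2-s (TDA)
#' window sets are gated independently: each score is present only if its
#' own passed windows cover at least `usable_min_seconds`. When a gate
#' fails the score is missing and the `reason` column says so
#' (`"usable<30s"`); nothing is silently partial. For 500 Hz devices the
#' record is decimated to `tda$decimate_to_hz` (after filtering) before
#' embedding, so point clouds are comparable across devices; the spectral
#' score always uses the native rate.
#'
#' @param record An [eeg_record()].
#' @param config A [bseeg_config()].
#' @param scores Which scores to compute (`"bseeg"`, `"tda"` or both);
#'   a score not requested is reported missing with reason
#'   `"not requested"`.
#' @return One-row data frame in the score-table layout
#'   (`subject_id, channel, delirium_label, bseeg_score, tda_score,
#'   n_windows_total, n_windows_passed`) plus a `reason` column; the
#'   per-duration window counts are attached as attribute
#'   `"window_counts"`.
#' @export
score_subject <- function(record, config = bseeg_config(),
                          scores = c("bseeg", "tda")) {
  stopifnot(inherits(record, "eeg_record"),
            all(scores %in% c("bseeg", "tda")), length(scores) >= 1L)
  filt <- bandpass_filter(record, config$filter$low_cut,
                          config$filter$high_cut, config$filter$order)

  ws_b <- qc_windows(segment_windows(filt, config$windows$bseeg_seconds),
                     config$qc)
  tda_rec <- filt
  dec <- config$tda$decimate_to_hz
  if (!is.null(dec) && filt$sampling_rate > dec &&
      filt$sampling_rate %% dec == 0) {
    tda_rec <- decimate_record(filt, filt$sampling_rate / dec)
  }
  ws_t <- qc_windows(segment_windows(tda_rec, config$windows$tda_seconds),
                     config$qc)

  gate <- config$usable_min_seconds
  reasons <- character(0)
  bseeg_score <- NA_real_
  if (!"bseeg" %in% scores) {
    reasons <- c(reasons, "bseeg:not requested")
  } else if (usable(ws_b, gate)) {
    passed <- which(ws_b$qc_status == "passed")
    wscores <- vapply(passed, function(j) {
      bseeg_window_score(ws_b$samples[, j], ws_b$sampling_rate, config$bseeg)
    }, numeric(1))
    bseeg_score <- aggregate_bseeg(wscores, config$bseeg)
  } else {
    reasons <- c(reasons, sprintf("bseeg:usable<%gs", gate))
  }
  tda_score <- NA_real_
  if (!"tda" %in% scores) {
    reasons <- c(reasons, "tda:not requested")
  } else if (usable(ws_t, gate)) {
    passed <- which(ws_t$qc_status == "passed")
    wscores <- vapply(passed, function(j) {
      tda_window_score(ws_t$samples[, j], ws_t$sampling_rate, config$tda)
    }, numeric(1))
    tda_score <- aggregate_tda(wscores, config$tda)
  } else {
    reasons <- c(reasons, sprintf("tda:usable<%gs", gate))
  }
  reason <- if (length(reasons) == 2L &&
                all(grepl("usable", reasons, fixed = TRUE))) {
    sprintf("usable<%gs", gate)     # both gates failed for the same cause
  } else if (length(reasons) >= 1L) {
    paste(reasons, collapse = ";")
  } else {
    NA_character_
  }

  row <- data.frame(
    subject_id = record$subject_id, channel = record$channel,
    delirium_label = NA_integer_, bseeg_score = bseeg_score,
    tda_score = tda_score,
    n_windows_total = ncol(ws_b$samples) + ncol(ws_t$samples),
    n_windows_passed = sum(ws_b$qc_status == "passed") +
      sum(ws_t$qc_status == "passed"),
    reason = reason, stringsAsFactors = FALSE)
  attr(row, "window_counts") <- data.frame(
    duration = c(config$windows$bseeg_seconds, config$windows$tda_seconds),
    n_total = c(ncol(ws_b$samples), ncol(ws_t$samples)),
    n_passed = c(sum(ws_b$qc_status == "passed"),
                 sum(ws_t$qc_status == "passed")))
  row
}

#' Score a list of records into a score table
#'
#' @param records List of [eeg_record()] objects.
#' @param config A [bseeg_config()].
#' @param scores Which scores to compute, as in [score_subject()].
#' @return Data frame with one row per record (the [score_subject()]
#'   layout), with a run manifest (config snapshot, package version,
#'   per-subject per-duration window counts, timestamp) attached as
#'   attribute `"manifest"`.
#' @export
score_cohort <- function(records, config = bseeg_config(),
                         scores = c("bseeg", "tda")) {
  rows <- lapply(records, score_subject, config = config, scores = scores)
  out <- do.call(rbind, rows)
  counts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    wc <- attr(rows[[i]], "window_counts")
    wc$subject_id <- out$subject_id[i]
    wc$channel <- out$channel[i]
    wc
  }))
  attr(out, "manifest") <- list(
    package_version = as.character(utils::packageVersion("bseegtda")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    window_counts = counts)
  out
}

#' Evaluate a labeled score table
#'
#' Joins scores to labels by `subject_id`, then, per channel: drops missing
#' scores per analysis (a subject missing only the TDA score still counts
#' for the BSEEG AUC), computes each score's ROC/AUC with DeLong CI, the
#' paired DeLong test on subjects with both scores, and the operating
#' point at the target sensitivity.
#'
#' @param scores Score table (from [score_cohort()] or [read_scores()]).
#' @param labels Either `NULL` (use the table's own `delirium_label`), or a
#'   data frame with `subject_id` plus `delirium_label` — or the raw
#'   assessments `cam_icu`, `drs`, `doss` (and optionally
#'   `chart_delirium`), which are converted via [label_delirium()].
#' @param target_sensitivity Operating-point sensitivity (default 0.80).
#' @return A `cohort_evaluation`: per channel, `auc_bseeg` and `auc_tda`
#'   ([roc_auc()] results), `delong` ([delong_paired_test()] result),
#'   `operating_point` per score, and the analysis sizes.
#' @export
evaluate_cohort <- function(scores, labels = NULL, target_sensitivity = 0.80) {
  stopifnot(is.data.frame(scores))
  if (!is.null(labels)) {
    stopifnot(is.data.frame(labels), "subject_id" %in% names(labels))
    if (!"delirium_label" %in% names(labels)) {
      need <- c("cam_icu", "drs", "doss")
      if (!all(need %in% names(labels))) {
        stop("labels need either `delirium_label` or `cam_icu`,`drs`,`doss`")
      }
      chart <- if ("chart_delirium" %in% names(labels)) {
        as.logical(labels$chart_delirium)
      } else FALSE
      labels$delirium_label <- as.integer(
        label_delirium(labels$cam_icu, labels$drs, labels$doss, chart))
    }
    unmatched <- setdiff(scores$subject_id, labels$subject_id)
    if (length(unmatched)) {
      stop("no label for subject(s): ", paste(unmatched, collapse = ", "))
    }
    scores$delirium_label <-
      labels$delirium_label[match(scores$subject_id, labels$subject_id)]
  }
  if (anyNA(scores$delirium_label)) {
    stop("missing delirium_label for subject(s): ",
         paste(scores$subject_id[is.na(scores$delirium_label)],
               collapse = ", "))
  }

  per_channel <- lapply(split(scores, scores$channel), function(df) {
    db <- df[!is.na(df$bseeg_score), ]
    dt <- df[!is.na(df$tda_score), ]
    dp <- df[!is.na(df$bseeg_score) & !is.na(df$tda_score), ]
    roc_b <- roc_auc(db$bseeg_score, db$delirium_label)
    roc_t <- roc_auc(dt$tda_score, dt$delirium_label)
    list(
      channel = df$channel[1L],
      n_scored = c(bseeg = nrow(db), tda = nrow(dt), paired = nrow(dp)),
      auc_bseeg = roc_b,
      auc_tda = roc_t,
      delong = delong_paired_test(dp$bseeg_score, dp$tda_score,
                                  dp$delirium_label),
      operating_point = list(
        bseeg = specificity_at_sensitivity(roc_b, target_sensitivity),
        tda = specificity_at_sensitivity(roc_t, target_sensitivity)),
      target_sensitivity = target_sensitivity)
  })
  structure(per_channel, class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  for (ch in x) {
    cat(sprintf("Channel %s (n: %d BSEEG, %d TDA, %d paired)\n",
                ch$channel, ch$n_scored[["bseeg"]], ch$n_scored[["tda"]],
                ch$n_scored[["paired"]]))
    cat(sprintf("  AUC  BSEEG %.3f (%.3f-%.3f)   TDA %.3f (%.3f-%.3f)\n",
                ch$auc_bseeg$auc, ch$auc_bseeg$ci_low, ch$auc_bseeg$ci_high,
                ch$auc_tda$auc, ch$auc_tda$ci_low, ch$auc_tda$ci_high))
    cat(sprintf("  DeLong (BSEEG - TDA): z = %.3f, p = %.4g%s\n",
                ch$delong$z, ch$delong$p,
                if (ch$delong$degenerate) " [degenerate]" else ""))
    cat(sprintf("  At sensitivity >= %.2f: specificity BSEEG %.2f, TDA %.2f\n",
                ch$target_sensitivity,
                ch$operating_point$bseeg$specificity,
                ch$operating_point$tda$specificity))
  }
  invisible(x)
}

#' Write a cohort evaluation as a JSON report
#'
#' @param evaluation A `cohort_evaluation` from [evaluate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "cohort_evaluation"))
  strip <- lapply(unclass(evaluation), function(ch) {
    ch$auc_bseeg <- ch$auc_bseeg[c("auc", "ci_low", "ci_high", "n_pos", "n_neg")]
    ch$auc_tda <- ch$auc_tda[c("auc", "ci_low", "ci_high", "n_pos", "n_neg")]
    ch$n_scored <- as.list(ch$n_scored)
    ch
  })
  jsonlite::write_json(strip, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
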