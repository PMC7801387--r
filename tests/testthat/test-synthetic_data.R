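# The generator is first-class code: these tests pin its spectral content,
# artifact behaviour and reproducibility.

clean <- function(slowing, seed, fs = 128, dur = 60) {
  simulate_eeg(sampling_rate = fs, duration = dur, slowing = slowing,
               artifact_rates = c(), seed = seed)
}

passed_window_scores <- function(rec) {
  ws <- qc_windows(segment_windows(bandpass_filter(rec), 4))
  vapply(which(ws$qc_status == "passed"), function(j) {
    bseeg_window_score(ws$samples[, j], ws$sampling_rate)
  }, numeric(1))
}

test_that("generation is deterministic and leaves the caller's RNG alone", {
  r1 <- simulate_eeg(duration = 10, seed = 42)
  set.seed(999)
  before <- .Random.seed
  r2 <- simulate_eeg(duration = 10, seed = 42)
  expect_identical(r1$samples, r2$samples)
  expect_identical(before, .Random.seed)
  expect_false(identical(r1$samples,
                         simulate_eeg(duration = 10, seed = 43)$samples))
})

test_that("fully slowed signals score positive, normal ones negative, per window", {
  for (seed in 1:3) {
    expect_true(all(passed_window_scores(clean(1, seed)) > 0))
    expect_true(all(passed_window_scores(clean(0, seed)) < 0))
  }
})

test_that("spectral balance between the 3 and 10 Hz bins tracks the slowing index", {
  bin_powers <- function(rec) {
    ws <- qc_windows(segment_windows(bandpass_filter(rec), 4))
    t(vapply(which(ws$qc_status == "passed"), function(j) {
      ps <- periodogram(ws$samples[, j], ws$sampling_rate)
      c(lo = ps$density[which.min(abs(ps$frequency - 3))],
        hi = ps$density[which.min(abs(ps$frequency - 10))])
    }, numeric(2)))
  }
  normal <- bin_powers(clean(0, 7))
  expect_gte(mean(normal[, "hi"] > normal[, "lo"]), 0.95)
  slowed <- bin_powers(clean(1, 7))
  expect_gte(mean(slowed[, "lo"] > slowed[, "hi"]), 0.95)
})

test_that("mean subject score is monotone in the slowing index", {
  for (seed in c(2, 5)) {
    means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
      mean(passed_window_scores(clean(s, seed, dur = 40)))
    }, numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("EMG bursts are rejected by QC", {
  rec <- clean(0, 13)
  burst <- inject_artifact(rec, "emg", seed = 5, amplitude = 400, at = 10)
  ws <- qc_windows(segment_windows(bandpass_filter(burst), 2))
  bad <- ws$qc_reason[ws$qc_status == "rejected"]
  expect_gte(length(bad), 1)
  expect_true(all(bad %in% c("amplitude", "high_freq_power")))
})

test_that("flatline spans knock out consecutive windows", {
  rec <- clean(0, 14)
  flat <- inject_artifact(rec, "flatline", seed = 6, duration = 5, at = 20.0)
  ws <- qc_windows(segment_windows(bandpass_filter(flat), 2))
  flat_idx <- which(ws$qc_reason == "flatline")
  expect_gte(length(flat_idx), 2)
  expect_true(any(diff(flat_idx) == 1))   # consecutive windows
})

test_that("in-band scores survive baseline drift thanks to the high-pass", {
  rec <- clean(0, 15)
  drift <- inject_artifact(rec, "drift", seed = 7, amplitude = 120,
                           duration = 15, at = 5)
  s_clean <- median(passed_window_scores(rec))
  s_drift <- median(passed_window_scores(drift))
  expect_lt(abs(s_drift - s_clean) / abs(s_clean), 0.10)
})

test_that("unknown artifact kinds are rejected", {
  expect_error(inject_artifact(clean(0, 1, dur = 5), "blink"), "unknown artifact")
})

test_that("cohorts reproduce their group structure", {
  sim <- simulate_cohort(4, 5, seed = 8, duration = 5)
  expect_length(sim$records, 9)
  expect_equal(sum(sim$cohort$delirium_label), 4)
  expect_equal(sum(sim$cohort$delirium_label == 0), 5)
  expect_equal(vapply(sim$records, `[[`, character(1), "subject_id"),
               sim$cohort$subject_id)
  expect_true(all(sim$cohort$slowing >= 0 & sim$cohort$slowing <= 1))
  sim2 <- simulate_cohort(4, 5, seed = 8, duration = 5)
  expect_identical(sim$records[[3]]$samples, sim2$records[[3]]$samples)
})

test_that("wider group separation yields higher BSEEG AUC", {
  auc_for <- function(gap, seed = 26) {
    sim <- simulate_cohort(10, 10, s_delirious = 0.5 + gap / 2,
                           s_control = 0.5 - gap / 2, seed = seed,
                           duration = 40)
    scores <- vapply(sim$records,
                     function(r) median(passed_window_scores(r)), numeric(1))
    roc_auc(scores, sim$cohort$delirium_label)$auc
  }
  aucs <- vapply(c(0.1, 0.4, 0.8), auc_for, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("slowed recordings carry higher TDA irregularity than normal ones", {
  tda_of <- function(slowing, seed) {
    rec <- simulate_eeg(duration = 40, slowing = slowing,
                        artifact_rates = c(), seed = seed)
    score_subject(rec, scores = "tda")$tda_score
  }
  for (seed in c(1, 7, 19)) {
    expect_gt(tda_of(1, seed), tda_of(0, seed + 100))
  }
})
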